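# Tail-based outlier detection and predictor assignment.

# Build an RDAModel shell with prescribed loadings for detector tests.
modelWithLoadings <- function(V, isKar = NULL) {
  if (is.null(isKar)) isKar <- logical(nrow(V))
  k <- ncol(V)
  new("RDAModel", eig = rev(seq_len(k)) + 0.0, eigResid = 1,
      totalInertia = k + 1, constrainedInertia = k,
      unconstrainedInertia = 1, pve = rep(1 / k, k),
      locusScores = V, sampleScores = matrix(0, 2, k),
      biplotScores = matrix(0, 1, k), rank = as.integer(k),
      nSamples = 2L, nPredictors = 1L, isKaryotype = isKar)
}

test_that("2.5% tails flag exactly 25 + 25 of 1000 distinct loadings", {
  set.seed(71)
  v <- matrix(sort(rnorm(1000)), dimnames = list(paste0("L", 1:1000), "RDA1"))
  rep_ <- detectOutliers(modelWithLoadings(v), sigAxes = 1, tail = 0.025)
  expect_equal(nrow(rep_), 50L)
  expect_equal(sum(rep_$tail == "lower"), 25L)
  expect_equal(sum(rep_$tail == "upper"), 25L)
  # sort-and-slice oracle: the extreme 25 per side
  ord <- order(v[, 1])
  oracle <- rownames(v)[c(ord[1:25], ord[976:1000])]
  expect_setequal(rep_$locus_id, oracle)
})

test_that("tied loadings at the boundary are not flagged", {
  v <- matrix(rep(0.3, 100), dimnames = list(paste0("L", 1:100), "RDA1"))
  rep_ <- detectOutliers(modelWithLoadings(v), sigAxes = 1, tail = 0.025)
  expect_equal(nrow(rep_), 0L)
})

test_that("flagged sets equal the sorting oracle on random loadings", {
  for (seed in c(3, 5, 9)) {
    set.seed(seed)
    L <- sample(200:800, 1)
    tail <- sample(c(0.01, 0.025, 0.05), 1)
    v <- matrix(rnorm(L), dimnames = list(paste0("L", seq_len(L)), "RDA1"))
    rep_ <- detectOutliers(modelWithLoadings(v), 1, tail = tail)
    q <- quantile(v[, 1], c(tail, 1 - tail), type = 7)
    oracle <- rownames(v)[v[, 1] < q[1] | v[, 1] > q[2]]
    expect_setequal(rep_$locus_id, oracle)
  }
})

test_that("detection is invariant under axis sign flip", {
  set.seed(72)
  v <- matrix(rnorm(400), 200, 2,
              dimnames = list(paste0("L", 1:200), c("RDA1", "RDA2")))
  a <- detectOutliers(modelWithLoadings(v), 1:2, tail = 0.05)
  b <- detectOutliers(modelWithLoadings(-v), 1:2, tail = 0.05)
  expect_setequal(a$locus_id, b$locus_id)
  merged <- merge(a, b, by = "locus_id")
  expect_true(all(merged$tail.x != merged$tail.y))   # labels swap
})

test_that("multi-axis hits deduplicate to the largest-|loading| axis", {
  v <- cbind(RDA1 = c(10, 0.1, 0.2, 0.3, 0.4, 0.5, -0.1, -0.2, -9, 0),
             RDA2 = c(4, 0.1, 0.2, 0.3, 0.4, 0.5, -0.1, -0.2, -20, 0))
  rownames(v) <- paste0("L", 1:10)
  rep_ <- detectOutliers(modelWithLoadings(v), 1:2, tail = 0.15)
  expect_equal(rep_$axis[rep_$locus_id == "L1"], 1)
  expect_equal(rep_$axis[rep_$locus_id == "L9"], 2)
  expect_false(any(duplicated(rep_$locus_id)))
  expect_gt(nrow(attr(rep_, "perAxis")), nrow(rep_))
})

test_that("too few loci for the tail still computes, with a warning", {
  v <- matrix(seq(-1, 1, length.out = 10),
              dimnames = list(paste0("L", 1:10), "RDA1"))
  expect_warning(rep_ <- detectOutliers(modelWithLoadings(v), 1,
                                        tail = 0.025), "poorly resolved")
  expect_true(is.data.frame(rep_))
})

test_that("assignment picks the most correlated predictor", {
  set.seed(73)
  n <- 40
  bio6 <- rnorm(n); bio16 <- rnorm(n)
  X <- cbind(BIO16 = bio16, BIO6 = bio6)
  Y <- cbind(hit6 = bio6, noise = rnorm(n),
             mix = 0.9 * scale(bio16)[, 1] + 0.1 * rnorm(n))
  rep_ <- data.frame(locus_id = c("hit6", "mix"), axis = 1L,
                     loading = c(1, -1), tail = "upper",
                     is_karyotype = FALSE, stringsAsFactors = FALSE)
  out <- assignPredictors(rep_, Y, X)
  expect_equal(out$best_predictor, c("BIO6", "BIO16"))
  expect_equal(out$r_best[1], 1, tolerance = 1e-12)
  # matches the brute-force all-pairs table
  allR <- abs(cor(Y[, rep_$locus_id], X))
  expect_equal(out$best_predictor,
               colnames(X)[apply(allR, 1, which.max)])
})

test_that("assignment ties break alphabetically and errors are raised", {
  n <- 30
  x <- rnorm(n)
  X <- cbind(ZVAR = x, AVAR = x)           # perfect tie
  Y <- cbind(loc = x)
  rep_ <- data.frame(locus_id = "loc", axis = 1L, loading = 1,
                     tail = "upper", is_karyotype = FALSE,
                     stringsAsFactors = FALSE)
  expect_message(out <- assignPredictors(rep_, Y, X), "tie")
  expect_equal(out$best_predictor, "AVAR")
  # zero-variance locus column
  Yz <- cbind(loc = rep(1, n))
  expect_error(assignPredictors(rep_, Yz, X), "zero-variance")
  # unknown locus id
  rep2 <- rep_; rep2$locus_id <- "nope"
  expect_error(assignPredictors(rep2, Y, X), "absent")
})

test_that("karyotype status reports flag, axis and best predictor", {
  rep_ <- data.frame(locus_id = c("SNP1", "KARYOTYPE"), axis = c(1L, 1L),
                     loading = c(0.5, -0.8), tail = c("upper", "lower"),
                     is_karyotype = c(FALSE, TRUE),
                     best_predictor = c("BIO16", "BIO6"),
                     r_best = c(0.4, -0.9), stringsAsFactors = FALSE)
  st <- karyotypeStatus(rep_)
  expect_true(st$flagged)
  expect_equal(st$best_predictor, "BIO6")
  expect_equal(st$loading, -0.8)
  # median loading -> not in the report -> not flagged
  st2 <- karyotypeStatus(rep_[1, , drop = FALSE])
  expect_false(st2$flagged)
  expect_error(karyotypeStatus(data.frame(locus_id = "x")),
               "is_karyotype")
})

test_that("per-axis flagged fraction never exceeds twice the tail", {
  for (seed in c(2, 4)) {
    set.seed(seed)
    v <- matrix(rnorm(600), 300, 2,
                dimnames = list(paste0("L", 1:300), c("RDA1", "RDA2")))
    rep_ <- detectOutliers(modelWithLoadings(v), 1:2, tail = 0.025)
    perAxis <- attr(rep_, "perAxis")
    for (ax in 1:2)
      expect_lte(sum(perAxis$axis == ax), 2 * 0.025 * 300 + 1)
  }
})
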