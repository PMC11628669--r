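# The constrained-ordination engine against trivial cases, the brute-force
# oracle, and vegan as an independent implementation.

test_that("a response equal to a single predictor is fully constrained", {
  set.seed(51)
  x <- rnorm(20)
  Y <- matrix(x, 20, 1)
  m <- fitRDA(Y, cbind(x = x))
  expect_equal(m@constrainedInertia, m@totalInertia, tolerance = 1e-10)
  expect_equal(length(m@eig), 1L)
  expect_equal(m@pve[1], 1)
})

test_that("predictors orthogonal to the response explain nothing", {
  n <- 12
  basis <- qr.Q(qr(scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)))
  Y <- basis[, 1:3] %*% matrix(rnorm(9), 3, 3)      # lives in cols 1-3
  X <- basis[, 4:5]                                  # orthogonal block
  colnames(X) <- c("a", "b")
  m <- fitRDA(Y, X)
  expect_equal(m@constrainedInertia, 0, tolerance = 1e-12)
})

test_that("eigenvalues, scores and inertia match the brute-force oracle", {
  for (seed in 1:20) {
    inst <- randomInstance(seed)
    m <- fitRDA(inst$Y, inst$X)
    o <- rdaOracle(inst$Y, inst$X)
    expect_equal(m@eig, o$eig, tolerance = 1e-8)
    expect_equal(m@totalInertia, o$total, tolerance = 1e-10)
    expect_equal(m@constrainedInertia, o$constrained, tolerance = 1e-8)
    for (k in seq_along(m@eig)) {
      if (m@eig[k] < 1e-8) next
      dev <- min(max(abs(m@locusScores[, k] - o$vectors[, k])),
                 max(abs(m@locusScores[, k] + o$vectors[, k])))
      expect_lt(dev, 1e-6)
    }
  }
})

test_that("eigenvalues and inertia agree with vegan's rda", {
  for (seed in c(5, 17)) {
    inst <- randomInstance(seed, n = 30, L = 50, p = 3)
    m <- fitRDA(inst$Y, inst$X)
    v <- vegan::rda(inst$Y ~ ., data = as.data.frame(inst$X))
    expect_equal(unname(m@eig), unname(v$CCA$eig), tolerance = 1e-8)
    expect_equal(m@totalInertia, v$tot.chi, tolerance = 1e-10)
    expect_equal(m@constrainedInertia, v$CCA$tot.chi, tolerance = 1e-8)
  }
})

test_that("inertia decomposition is conserved and axes are orthogonal", {
  for (seed in 21:30) {
    inst <- randomInstance(seed)
    m <- fitRDA(inst$Y, inst$X)
    expect_equal(m@constrainedInertia + m@unconstrainedInertia,
                 m@totalInertia,
                 tolerance = 1e-8 * max(1, m@totalInertia))
    expect_true(all(diff(m@eig) <= 1e-12))
    expect_true(all(m@eig > -1e-10))
    expect_equal(sum(m@pve), 1, tolerance = 1e-10)
    S <- m@sampleScores
    cv <- cov(S)
    offdiag <- cv[upper.tri(cv)]
    expect_lt(max(abs(offdiag)), 1e-8 * max(1, max(diag(cv))))
  }
})

test_that("a saturated model (p = n - 1) reaches the total inertia", {
  set.seed(52)
  n <- 8
  Y <- matrix(rnorm(n * 20), n, 20)
  X <- matrix(rnorm(n * (n - 1)), n, n - 1)
  m <- fitRDA(Y, X)
  expect_equal(m@constrainedInertia, m@totalInertia,
               tolerance = 1e-8 * m@totalInertia)
})

test_that("joint row permutation leaves eigenvalues unchanged", {
  inst <- randomInstance(31, n = 25, L = 30, p = 3)
  set.seed(53)
  perm <- sample(25)
  m1 <- fitRDA(inst$Y, inst$X)
  m2 <- fitRDA(inst$Y[perm, ], inst$X[perm, ])
  expect_equal(m1@eig, m2@eig, tolerance = 1e-10)
})

test_that("axis signs follow the largest-|loading|-positive convention", {
  inst <- randomInstance(32, n = 30, L = 40, p = 3)
  m <- fitRDA(inst$Y, inst$X)
  for (k in seq_len(m@rank))
    expect_gt(m@locusScores[which.max(abs(m@locusScores[, k])), k], 0)
})

test_that("rank-deficient predictors are rejected naming the column", {
  set.seed(54)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fitRDA(matrix(rnorm(20 * 5), 20, 5), X), "dup")
})

test_that("pseudo-F matches the inertia-ratio definition", {
  # direct arithmetic: constrained 2, unconstrained 8, n = 21, p = 2
  m <- new("RDAModel", eig = 2, eigResid = 8, totalInertia = 10,
           constrainedInertia = 2, unconstrainedInertia = 8,
           pve = 1, locusScores = matrix(0, 1, 1),
           sampleScores = matrix(0, 1, 1), biplotScores = matrix(0, 1, 1),
           rank = 1L, nSamples = 21L, nPredictors = 2L,
           isKaryotype = FALSE)
  expect_equal(pseudoF(m)$statistic, 2.25)
  expect_equal(pseudoF(m)$df_resid, 18L)
  # recomputation oracle on random instances
  for (seed in c(6, 8)) {
    inst <- randomInstance(seed, n = 30, L = 40, p = 4)
    m2 <- fitRDA(inst$Y, inst$X)
    o <- rdaOracle(inst$Y, inst$X)
    Fo <- (o$constrained / 4) / (o$unconstrained / (30 - 4 - 1))
    expect_equal(pseudoF(m2)$statistic, Fo, tolerance = 1e-8)
  }
  # degenerate: zero constrained inertia -> F = 0
  n <- 12
  basis <- qr.Q(qr(scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)))
  m3 <- fitRDA(basis[, 1:3] %*% matrix(rnorm(9), 3, 3),
               cbind(a = basis[, 4], b = basis[, 5]))
  expect_equal(pseudoF(m3)$statistic, 0, tolerance = 1e-12)
})

test_that("biplot scores are predictor-axis correlations", {
  inst <- randomInstance(33, n = 30, L = 40, p = 3)
  m <- fitRDA(inst$Y, inst$X)
  direct <- cor(scale(inst$X), m@sampleScores)
  expect_equal(unname(m@biplotScores), unname(direct), tolerance = 1e-10)
  # predictor equal to axis-1 scores -> biplot row (1, 0, ...)
  xnew <- cbind(ax1 = m@sampleScores[, 1], noise = rnorm(30))
  proj <- predictorAxisProjection(m, xnew)
  expect_equal(proj["ax1", 1], 1, tolerance = 1e-10)
  expect_lt(max(abs(proj["ax1", -1])), 1e-6)
})

test_that("population scores are per-population means of sample scores", {
  inst <- randomInstance(34, n = 20, L = 30, p = 2)
  m <- fitRDA(inst$Y, inst$X)
  popn <- rep(c("a", "b", "c", "d"), each = 5)
  ps <- populationScores(m, popn)
  expect_equal(unname(ps["b", ]),
               unname(colMeans(m@sampleScores[popn == "b", ])))
})
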