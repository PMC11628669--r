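# Coverage / MAF filters, mode imputation, karyotype append, and the
# one-per-cytotype subsample.

test_that("coverage filter keeps loci called in at least minCalled samples", {
  set.seed(21)
  m <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
  miss <- matrix(runif(20 * 50) < 0.4, 20, 50)
  m[miss] <- NA
  g <- toyGeno(m)
  for (thr in c(1L, 10L, 15L)) {
    kept <- locusMap(suppressMessages(filterCoverage(g, thr)))$locus_id
    oracle <- paste0("L", which(colSums(!is.na(m)) >= thr))
    expect_identical(kept, oracle)
  }
  # fully missing column removed at any threshold >= 1
  m2 <- m; m2[, 3] <- NA
  expect_false("L3" %in%
    locusMap(suppressMessages(filterCoverage(toyGeno(m2), 1L)))$locus_id)
})

test_that("MAF filter removes rare and monomorphic loci", {
  # 10 samples, one heterozygote -> MAF 0.05, removed at 0.10
  m <- cbind(c(1, rep(0, 9)),            # MAF 0.05
             rep(0, 10),                 # monomorphic
             c(rep(1, 4), rep(0, 6)),    # MAF 0.20
             rep(1, 10))                 # MAF 0.50
  g <- toyGeno(m)
  kept <- locusMap(suppressMessages(filterMAF(g, 0.10)))$locus_id
  expect_identical(kept, c("L3", "L4"))
  expect_identical(
    locusMap(suppressMessages(filterMAF(g, 1e-9)))$locus_id,
    c("L1", "L3", "L4"))
})

test_that("swept MAF columns recover the configured threshold boundary", {
  # columns with exact MAF k/40 for k = 0..20 over 20 samples
  cols <- sapply(0:20, function(k) c(rep(1, k), rep(0, 20 - k)))
  g <- toyGeno(cols)
  kept <- locusMap(suppressMessages(filterMAF(g, 0.10)))$locus_id
  mafs <- (0:20)[match(kept, paste0("L", 1:21))] / 40
  expect_equal(min(mafs), 0.10)   # smallest retained MAF == threshold
  removed <- setdiff(paste0("L", 1:21), kept)
  expect_true(all((match(removed, paste0("L", 1:21)) - 1) / 40 < 0.10))
})

test_that("filters commute when MAF is computed on non-missing calls", {
  set.seed(22)
  m <- matrix(sample(0:2, 30 * 40, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1)), 30, 40)
  m[matrix(runif(30 * 40) < 0.3, 30, 40)] <- NA
  g <- toyGeno(m)
  a <- suppressMessages(filterMAF(filterCoverage(g, 15L), 0.1))
  b <- suppressMessages(filterCoverage(filterMAF(g, 0.1), 15L))
  expect_identical(locusMap(a)$locus_id, locusMap(b)$locus_id)
})

test_that("mode imputation fills missing calls and alters nothing else", {
  m <- cbind(c(0, 0, 2, NA), c(1, 1, NA, 0), c(0, 1, 2, 0))
  g <- toyGeno(m)
  out <- suppressMessages(imputeMissing(g))
  expect_equal(unname(genoMatrix(out)[, 1]), c(0, 0, 2, 0))
  expect_equal(unname(genoMatrix(out)[, 2]), c(1, 1, 1, 0))
  expect_equal(unname(genoMatrix(out)[, 3]), m[, 3])  # identity when complete
  # imputed fraction equals input missingness
  set.seed(23)
  m2 <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  drop <- matrix(FALSE, 20, 10)
  drop[sample(200, 37)] <- TRUE
  m2na <- m2; m2na[drop] <- NA
  expect_message(out2 <- imputeMissing(toyGeno(m2na)), "37 missing")
  expect_false(anyNA(genoMatrix(out2)))
  # non-missing entries unaltered
  expect_identical(genoMatrix(out2)[!drop], m2[!drop])
})

test_that("appendKaryotype adds one flagged pseudo-locus column", {
  set.seed(24)
  m <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  twoN <- c(70L, 72L, 72L, 74L, 76L, 78L, 80L, 84L)
  g <- appendKaryotype(toyGeno(m, twoN = twoN))
  expect_equal(ncol(genoMatrix(g)), 6L)
  expect_equal(karyotypeIndex(g), 6L)
  kcol <- genoMatrix(g)[, 6]
  expect_equal(mean(kcol), 0, tolerance = 1e-12)
  expect_equal(sd(kcol), 1, tolerance = 1e-12)
  # raw scaling keeps 2n values
  graw <- appendKaryotype(toyGeno(m, twoN = twoN), scaling = "raw")
  expect_equal(unname(genoMatrix(graw)[, 6]), as.numeric(twoN))
  # degenerate: constant karyotype rejected
  expect_error(appendKaryotype(toyGeno(m, twoN = rep(72L, 8))),
               "zero variance")
  # samples lacking 2n are dropped with a message
  twoN2 <- twoN; twoN2[3] <- NA
  expect_message(g2 <- appendKaryotype(toyGeno(m, twoN = twoN2)),
                 "dropped")
  expect_equal(ncol(g2), 7L)  # loci x samples orientation: 7 samples left
})

test_that("cytotype subsample keeps one sample per (population, 2n) pair", {
  m <- matrix(sample(0:2, 9 * 4, replace = TRUE), 9, 4)
  pop <- c(rep("A", 5), rep("B", 3), "C")
  twoN <- c(72L, 72L, 72L, 74L, 74L,   # A: {72:3, 74:2} -> 2 kept
            76L, 76L, 78L,             # B: {76:2, 78:1} -> 2 kept
            80L)                       # C: singleton passes through
  g <- toyGeno(m, twoN = twoN, pop = pop)
  out <- suppressMessages(subsampleOnePerCytotype(g, seed = 5))
  sd_ <- sampleData(out)
  expect_equal(nrow(sd_), 5L)
  expect_equal(sort(paste(sd_$population, sd_$two_n)),
               c("A 72", "A 74", "B 76", "B 78", "C 80"))
  expect_true("s9" %in% sd_$sample_id)
  # size deterministic across seeds; membership may differ
  sizes <- vapply(1:10, function(s) ncol(suppressMessages(
    subsampleOnePerCytotype(g, seed = s))), numeric(1))
  expect_true(all(sizes == 5))
  # reproducible under a fixed seed
  a <- colnames(suppressMessages(subsampleOnePerCytotype(g, seed = 42)))
  b <- colnames(suppressMessages(subsampleOnePerCytotype(g, seed = 42)))
  expect_identical(a, b)
})

test_that("subsample size equals the distinct-pair count on synthetic data", {
  sim <- simulateLandscape(simConfig(nNeutral = 40L, nAdaptive = 0L,
                                     missingRate = 0, seed = 31L))
  g <- sim$geno
  out <- suppressMessages(subsampleOnePerCytotype(g, seed = 1))
  cd <- sampleData(g)
  expect_equal(ncol(out),
               nrow(unique(cd[, c("population", "two_n")])))
})
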