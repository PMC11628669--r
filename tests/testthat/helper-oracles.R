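# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (dense algebra, explicit loops,
# exhaustive agglomeration) so it stays independent of the package's code
# paths.

# Brute-force RDA: explicit normal-equations fit + full eigendecomposition
# of the fitted cross-product.  Returns eigenvalues, eigenvectors (locus
# loadings), and the inertia decomposition.
rdaOracle <- function(Y, X) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xs <- scale(X)
  B <- solve(t(Xs) %*% Xs) %*% t(Xs) %*% Yc
  Fit <- Xs %*% B
  ed <- eigen(t(Fit) %*% Fit / (n - 1), symmetric = TRUE)
  k <- min(ncol(X), n - 1, ncol(Y))
  total <- sum(apply(Y, 2, var))
  constrained <- sum(pmax(ed$values, 0))
  list(eig = ed$values[seq_len(k)],
       vectors = ed$vectors[, seq_len(k), drop = FALSE],
       total = total, constrained = constrained,
       unconstrained = total - constrained)
}

randomInstance <- function(seed, n = NULL, L = NULL, p = NULL,
                           signal = 0.5) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:40, 1)
  if (is.null(p)) p <- sample(2:5, 1)
  if (is.null(L)) L <- sample((p + 1):60, 1)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * L), n, L) +
    signal * (X %*% matrix(rnorm(p * L), p, L))
  list(Y = Y, X = X, n = n, L = L, p = p)
}

# Exhaustive complete-linkage agglomeration over name-sets: repeatedly merge
# the pair of clusters with the smallest complete-linkage distance while it
# is < cut.
completeLinkageOracle <- function(D, cut) {
  clusters <- as.list(colnames(D))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (bestd >= cut) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
  }
  lapply(clusters, sort)
}

# Weir & Cockerham (1984)-style multi-population FST, ratio of averages.
wcFst <- function(geno, pop) {
  pops <- unique(pop)
  r <- length(pops)
  num <- den <- 0
  for (l in seq_len(ncol(geno))) {
    x <- geno[, l]
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      xv <- x[pop == pops[k]]
      xv <- xv[!is.na(xv)]
      ni[k] <- length(xv)
      if (ni[k] == 0) next
      pi[k] <- mean(xv) / 2
      hi[k] <- mean(xv == 1)
    }
    ok <- ni > 0
    ni <- ni[ok]; pi <- pi[ok]; hi <- hi[ok]; rr <- sum(ok)
    if (rr < 2) next
    nbar <- mean(ni)
    nc <- (rr * nbar - sum(ni^2) / (rr * nbar)) / (rr - 1)
    pbar <- sum(ni * pi) / (rr * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((rr - 1) * nbar)
    hbar <- sum(ni * hi) / (rr * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (rr - 1) / rr * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (rr - 1) / rr * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# A tiny deterministic GenoExperiment built by hand.
toyGeno <- function(geno, twoN = NULL, pop = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  if (is.null(pop)) pop <- rep("P1", n)
  samples <- data.frame(sample_id = paste0("s", seq_len(n)),
                        population = pop, species = "sp",
                        latitude = seq_len(n), longitude = 0,
                        two_n = if (is.null(twoN)) NA_integer_ else twoN)
  lmap <- data.frame(locus_id = paste0("L", seq_len(L)),
                     contig = "ctg1", position = seq_len(L) * 100L)
  dimnames(geno) <- list(samples$sample_id, lmap$locus_id)
  GenoExperiment(geno, lmap, samples)
}

writeLinesTmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal VCF fixture: genotypes is loci x samples list of GT strings.
vcfFixture <- function(rows, samples) {
  writeLinesTmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    rows), ".vcf")
}

gffFixture <- function(rows) {
  writeLinesTmp(c("##gff-version 3", rows), ".gff3")
}
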