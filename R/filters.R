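## Locus filters and karyotype handling.  The chromosome-number pseudo-locus
## is exempt from coverage/MAF filtering but is treated identically to a SNP
## by every downstream step (ordination, outlier scan, predictor
## assignment).

#' Coverage filter
#'
#' Keeps SNP loci called (non-missing) in at least \code{minCalled} samples.
#' The karyotype pseudo-locus, when present, is always retained.  Locus
#' order is preserved.
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param minCalled minimum number of non-missing genotypes per locus
#'   (default 100)
#' @return filtered \linkS4class{GenoExperiment}
#' @export
filterCoverage <- function(g, minCalled = 100L) {
    stopifnot(minCalled <= ncol(g))
    called <- rowSums(!is.na(assay(g, "geno")))
    keep <- called >= minCalled | rowData(g)$is_karyotype
    message(sprintf("coverage filter (>= %d called): %d -> %d loci",
                    minCalled, nrow(g), sum(keep)))
    g[keep, ]
}

## minor-allele frequency per locus over non-missing calls
.mafOf <- function(g) {
    m <- assay(g, "geno")
    f <- rowSums(m, na.rm = TRUE) / (2 * rowSums(!is.na(m)))
    pmin(f, 1 - f)
}

#' Minor allele frequency filter
#'
#' Keeps SNP loci whose MAF, computed over non-missing genotypes as an
#' allele-count fraction, is at least \code{mafMin}.  The karyotype
#' pseudo-locus is exempt.
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param mafMin minimum minor allele frequency in [0, 0.5] (default 0.10)
#' @return filtered \linkS4class{GenoExperiment}
#' @export
filterMAF <- function(g, mafMin = 0.10) {
    stopifnot(mafMin >= 0, mafMin <= 0.5)
    maf <- .mafOf(g)
    keep <- (!is.na(maf) & maf >= mafMin) | rowData(g)$is_karyotype
    message(sprintf("MAF filter (>= %.3f): %d -> %d loci",
                    mafMin, nrow(g), sum(keep)))
    g[keep, ]
}

#' Mode imputation of missing genotypes
#'
#' Replaces each missing call by the per-locus most common genotype value
#' (ties broken toward the smaller count).  Non-missing entries are never
#' altered.  The karyotype pseudo-locus row, if present, is imputed by its
#' rounded mean instead (its support is not \{0,1,2\}).
#'
#' @param g a \linkS4class{GenoExperiment}
#' @return complete \linkS4class{GenoExperiment}
#' @export
imputeMissing <- function(g) {
    m <- assay(g, "geno")
    nmiss <- sum(is.na(m))
    kar <- rowData(g)$is_karyotype
    for (i in seq_len(nrow(m))) {
        miss <- is.na(m[i, ])
        if (!any(miss)) next
        if (all(miss))
            stop("all-missing locus: ", rownames(m)[i])
        if (kar[i]) {
            m[i, miss] <- round(mean(m[i, !miss]))
        } else {
            tab <- tabulate(m[i, !miss] + 1L, nbins = 3L)
            m[i, miss] <- which.max(tab) - 1L
        }
    }
    message(sprintf("imputed %d missing call(s) (%.2f%% of matrix)",
                    nmiss, 100 * nmiss / length(m)))
    assay(g, "geno") <- m
    g
}

#' Append the chromosome number as a pseudo-locus
#'
#' Adds one row holding each sample's diploid chromosome number (2n), flagged
#' \code{is_karyotype}, so karyotype variation enters the ordination and the
#' outlier scan exactly like a SNP.  Samples lacking a chromosome count are
#' dropped (with a message).  By default the column is centered and scaled
#' to unit variance so a pseudo-locus on the 69-84 scale cannot dominate the
#' total inertia of 0-2 SNP columns; \code{scaling = "raw"} keeps the 2n
#' values for sensitivity analysis.
#'
#' @param g a \linkS4class{GenoExperiment} whose colData carries \code{two_n}
#' @param scaling \code{"standardized"} (default) or \code{"raw"}
#' @return \linkS4class{GenoExperiment} with one extra locus
#' @export
appendKaryotype <- function(g, scaling = c("standardized", "raw")) {
    scaling <- match.arg(scaling)
    if (any(rowData(g)$is_karyotype))
        stop("karyotype pseudo-locus already present")
    twoN <- colData(g)$two_n
    if (all(is.na(twoN))) stop("all samples lack a chromosome number")
    if (anyNA(twoN)) {
        message(sum(is.na(twoN)),
                " sample(s) without chromosome number dropped")
        g <- g[, !is.na(twoN)]
        twoN <- colData(g)$two_n
    }
    rng <- metadata(g)$karyotypeRange
    if (!is.null(rng) && (any(twoN < rng[1]) || any(twoN > rng[2])))
        stop("chromosome numbers outside declared range [",
             rng[1], ", ", rng[2], "]")
    if (stats::sd(twoN) == 0)
        stop("karyotype column has zero variance (all 2n = ",
             twoN[1], ")")
    val <- if (scaling == "standardized") as.numeric(scale(twoN))
           else as.numeric(twoN)
    m <- rbind(assay(g, "geno"), KARYOTYPE = val)
    rd <- rbind(rowData(g),
                DataFrame(contig = NA_character_, position = NA_integer_,
                          is_karyotype = TRUE, row.names = "KARYOTYPE"))
    se <- SummarizedExperiment(assays = list(geno = m), rowData = rd,
                               colData = colData(g))
    out <- new("GenoExperiment", se)
    metadata(out) <- metadata(g)
    metadata(out)$karyotypeScaling <- scaling
    out
}

#' Subsample one representative per (population, cytotype)
#'
#' Mirrors the study design in which each sample within a population
#' represents a distinct chromosome number: for every (population, 2n) pair
#' with two or more samples one is selected at random; singletons pass
#' through.  Output size is deterministic (the number of distinct pairs);
#' membership depends on \code{seed}.
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param seed integer seed for the random selection
#' @return \linkS4class{GenoExperiment} restricted to the selected samples
#' @export
subsampleOnePerCytotype <- function(g, seed) {
    cd <- colData(g)
    if (anyNA(cd$two_n))
        stop("chromosome number must be known for all retained samples")
    key <- paste(cd$population, cd$two_n, sep = "\r")
    set.seed(seed)
    pick <- unlist(lapply(split(seq_len(ncol(g)), key), function(idx) {
        if (length(idx) == 1L) idx else sample(idx, 1L)
    }), use.names = FALSE)
    pick <- sort(pick)
    message(sprintf("cytotype subsample: %d -> %d samples (%d pop x 2n pairs)",
                    ncol(g), length(pick), length(unique(key))))
    g[, pick]
}
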