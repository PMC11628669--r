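## Redundancy analysis, written from first principles.
##
## Y (samples x loci) is column-centered; X (samples x predictors) is
## column-standardized.  The constrained part is the least-squares fit
## Yhat = X (X'X)^-1 X' Y; its singular value decomposition Yhat = U D V'
## yields eigenvalues d_k^2 / (n - 1), site scores U D (per-axis variance =
## eigenvalue), and raw-eigenvector locus loadings V.  Inertia is summed
## column variance (divisor n - 1) and decomposes exactly into
## constrained + unconstrained.

.centerCols <- function(M) sweep(M, 2, colMeans(M))

.standardizeCols <- function(M) {
    s <- apply(M, 2, stats::sd)
    if (any(s == 0))
        stop("zero-variance predictor: ",
             paste(colnames(M)[s == 0], collapse = ", "))
    scale(M)
}

## total inertia of an (uncentered) response matrix
.totalInertia <- function(Y) sum(apply(Y, 2, stats::var))

## constrained inertia of centered Yc on a column basis Q (orthonormal)
.constrainedInertiaQ <- function(Yc, Q) {
    sum((crossprod(Q, Yc))^2) / (nrow(Yc) - 1)
}

## rank-trimmed orthonormal basis (tolerates rank deficiency; used by the
## permutation machinery where deficient bases arise by construction)
.projBasis <- function(M) {
    qrm <- qr(M)
    qr.Q(qrm)[, seq_len(max(qrm$rank, 1L)), drop = FALSE]
}

## thin orthonormal basis of centered/standardized X
.basisOf <- function(Xs) {
    qrX <- qr(Xs)
    if (qrX$rank < ncol(Xs)) {
        dep <- colnames(Xs)[qrX$pivot[(qrX$rank + 1):ncol(Xs)]]
        stop("predictor matrix is rank deficient; dependent column(s): ",
             paste(dep, collapse = ", "))
    }
    qr.Q(qrX)
}

#' Fit a redundancy analysis
#'
#' @param Y response: a complete \linkS4class{GenoExperiment} (no missing
#'   calls) or a numeric samples x loci matrix.  Columns are centered, not
#'   standardized (0/1/2 counts share a scale; the karyotype pseudo-locus is
#'   standardized upstream by \code{\link{appendKaryotype}}).
#' @param X predictors: a \linkS4class{PredictorSet} or numeric samples x
#'   predictors matrix; columns are standardized.
#' @param isKaryotype optional logical per locus (filled automatically from
#'   a GenoExperiment response)
#' @return an \linkS4class{RDAModel}.  Axis signs follow the convention that
#'   the largest-magnitude locus loading on each axis is positive.
#' @export
fitRDA <- function(Y, X, isKaryotype = NULL) {
    if (is(Y, "GenoExperiment")) {
        if (is.null(isKaryotype))
            isKaryotype <- unname(rowData(Y)$is_karyotype)
        Y <- genoMatrix(Y)
    }
    Xm <- if (is(X, "PredictorSet")) predictorValues(X) else as.matrix(X)
    Y <- as.matrix(Y)
    if (anyNA(Y)) stop("response matrix has missing entries; impute first")
    n <- nrow(Y); L <- ncol(Y); p <- ncol(Xm)
    stopifnot(nrow(Xm) == n)
    if (n < p + 1) stop("need n >= p + 1 samples")
    if (is.null(isKaryotype)) isKaryotype <- logical(L)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("L", seq_len(L))
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("X", seq_len(p))

    Yc <- .centerCols(Y)
    Xs <- .standardizeCols(Xm)
    Q <- .basisOf(Xs)
    Yhat <- Q %*% crossprod(Q, Yc)

    k <- min(p, n - 1L, L)
    sv <- svd(Yhat, nu = k, nv = k)
    eig <- (sv$d[seq_len(k)]^2) / (n - 1)
    U <- sv$u; V <- sv$v
    ## sign convention: largest-|loading| locus positive per axis
    for (j in seq_len(k)) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
    }
    sampleScores <- U %*% diag(sv$d[seq_len(k)], nrow = k)
    dimnames(sampleScores) <- list(rownames(Y), paste0("RDA", seq_len(k)))
    dimnames(V) <- list(colnames(Y), paste0("RDA", seq_len(k)))

    total <- .totalInertia(Y)
    constrained <- sum(eig)
    resid <- Yc - Yhat
    dresid <- svd(resid, nu = 0, nv = 0)$d
    eigResid <- dresid^2 / (n - 1)
    eigResid <- eigResid[eigResid > max(eigResid[1], 1e-300) * 1e-12]
    unconstrained <- total - constrained

    bip <- .biplotFrom(Xs, sampleScores)
    new("RDAModel", eig = eig, eigResid = eigResid,
        totalInertia = total, constrainedInertia = constrained,
        unconstrainedInertia = unconstrained,
        pve = if (constrained > 0) eig / constrained else rep(0, k),
        locusScores = V, sampleScores = sampleScores,
        biplotScores = bip, rank = as.integer(k),
        nSamples = as.integer(n), nPredictors = as.integer(p),
        isKaryotype = isKaryotype)
}

.biplotFrom <- function(Xs, sampleScores) {
    keep <- apply(sampleScores, 2, stats::sd) > 0
    bip <- matrix(0, ncol(Xs), ncol(sampleScores),
                  dimnames = list(colnames(Xs), colnames(sampleScores)))
    if (any(keep))
        bip[, keep] <- stats::cor(Xs, sampleScores[, keep, drop = FALSE])
    bip
}

#' Pseudo-F statistic of a fitted RDA
#'
#' F = (constrained inertia / p) / (unconstrained inertia / (n - p - 1)),
#' the standard constrained-ordination statistic used by the permutation
#' tests.
#'
#' @param model an \linkS4class{RDAModel}
#' @return list with \code{statistic}, \code{df_model}, \code{df_resid}
#' @export
pseudoF <- function(model) {
    n <- model@nSamples; p <- model@nPredictors
    if (n <= p + 1) stop("residual degrees of freedom must be positive")
    list(statistic = (model@constrainedInertia / p) /
             (model@unconstrainedInertia / (n - p - 1)),
         df_model = p, df_resid = n - p - 1L)
}

#' Project predictors onto ordination axes
#'
#' Biplot score of predictor j on axis k = Pearson correlation of X_j with
#' the axis-k sample scores.  Recomputes the projection for an arbitrary
#' predictor table (the fitted model already stores the scores for its own
#' predictors).
#'
#' @param model an \linkS4class{RDAModel}
#' @param X a \linkS4class{PredictorSet} or numeric matrix aligned to the
#'   model's samples
#' @return predictors x axes matrix of correlations
#' @export
predictorAxisProjection <- function(model, X) {
    Xm <- if (is(X, "PredictorSet")) predictorValues(X) else as.matrix(X)
    stopifnot(nrow(Xm) == model@nSamples)
    .biplotFrom(scale(Xm), model@sampleScores)
}

#' Per-population mean sample scores
#'
#' Ordination plots in landscape genomics are often drawn at the population
#' level; this collapses per-sample site scores to population means.
#'
#' @param model an \linkS4class{RDAModel}
#' @param population character/factor of population labels, one per sample
#' @return populations x axes matrix
#' @export
populationScores <- function(model, population) {
    stopifnot(length(population) == model@nSamples)
    rowsum(model@sampleScores, population) /
        as.vector(table(population)[sort(unique(as.character(population)))])
}
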