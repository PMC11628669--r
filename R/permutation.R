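## Permutation significance tests for the constrained ordination: global
## model, marginal predictor (term) tests, and sequential axis tests.  All
## use the pseudo-F statistic and the add-one permutation p-value
## p = (1 + #{F* >= F_obs}) / (n_perm + 1).

.asYX <- function(Y, X) {
    if (is(Y, "GenoExperiment")) Y <- genoMatrix(Y)
    if (is(X, "PredictorSet")) X <- predictorValues(X)
    Y <- as.matrix(Y); X <- as.matrix(X)
    if (anyNA(Y)) stop("response matrix has missing entries; impute first")
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
    list(Y = Y, X = X)
}

.permIndex <- function(n, strata = NULL) {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (grp in split(seq_len(n), strata))
        idx[grp] <- grp[sample.int(length(grp))]
    idx
}

#' Global permutation test of the RDA model
#'
#' Permutes whole rows of the predictor matrix, refits, and compares the
#' observed pseudo-F to the permutation distribution.
#'
#' @param Y response (\linkS4class{GenoExperiment} or matrix, complete)
#' @param X predictors (\linkS4class{PredictorSet} or matrix)
#' @param nPerm number of permutations (default 1000)
#' @param seed integer seed
#' @param strata optional factor restricting permutations to within-group
#'   exchanges (e.g. population)
#' @return one-row data.frame: target, F, df_model, df_resid, p_value,
#'   n_perm, seed
#' @export
testGlobal <- function(Y, X, nPerm = 1000L, seed = 1L, strata = NULL) {
    stopifnot(nPerm >= 1L)
    d <- .asYX(Y, X)
    n <- nrow(d$Y); p <- ncol(d$X)
    Yc <- .centerCols(d$Y)
    Xs <- .standardizeCols(d$X)
    total <- .totalInertia(d$Y)
    fOf <- function(Xrow) {
        ci <- .constrainedInertiaQ(Yc, .projBasis(Xrow))
        (ci / p) / ((total - ci) / (n - p - 1))
    }
    Fobs <- fOf(Xs)
    set.seed(seed)
    Fstar <- vapply(seq_len(nPerm),
                    function(b) fOf(Xs[.permIndex(n, strata), ,
                                       drop = FALSE]),
                    numeric(1))
    data.frame(target = "global", F = Fobs, df_model = p,
               df_resid = n - p - 1L,
               p_value = (1 + sum(Fstar >= Fobs)) / (nPerm + 1),
               n_perm = nPerm, seed = seed, stringsAsFactors = FALSE)
}

#' Marginal permutation tests per predictor
#'
#' Tests each predictor's unique contribution given all others: the response
#' and the focal predictor are residualized on the remaining predictors and
#' the residualized predictor's rows are permuted.  Marginal (not
#' sequential) testing keeps the result invariant to predictor order.
#'
#' @inheritParams testGlobal
#' @return data.frame with one row per predictor (target = "term:<name>")
#' @export
testTerms <- function(Y, X, nPerm = 1000L, seed = 1L, strata = NULL) {
    stopifnot(nPerm >= 1L)
    d <- .asYX(Y, X)
    n <- nrow(d$Y); p <- ncol(d$X)
    Yc <- .centerCols(d$Y)
    Xs <- .standardizeCols(d$X)
    total <- .totalInertia(d$Y)
    dfr <- n - p - 1L
    out <- lapply(seq_len(p), function(j) {
        Xo <- Xs[, -j, drop = FALSE]
        Qo <- if (ncol(Xo)) .projBasis(Xo) else matrix(0, n, 0)
        cMinus <- if (ncol(Xo)) .constrainedInertiaQ(Yc, Qo) else 0
        Yr <- Yc - Qo %*% crossprod(Qo, Yc)
        xr <- Xs[, j] - Qo %*% crossprod(Qo, Xs[, j])
        ## a predictor duplicated by the others leaves no unique signal:
        ## its residual is numerically zero and F is identically 0 (p = 1)
        degenerate <- sum(xr^2) < 1e-10 * n
        cOf <- function(x) {
            if (degenerate) return(0)
            q <- x / sqrt(sum(x^2))
            sum((crossprod(q, Yr))^2) / (n - 1)
        }
        fOf <- function(cj) cj / ((total - cMinus - cj) / dfr)
        cObs <- cOf(xr)
        Fobs <- fOf(cObs)
        set.seed(seed + j)
        Fstar <- vapply(seq_len(nPerm), function(b)
            fOf(cOf(xr[.permIndex(n, strata)])), numeric(1))
        data.frame(target = paste0("term:", colnames(Xs)[j]), F = Fobs,
                   df_model = 1L, df_resid = dfr,
                   p_value = (1 + sum(Fstar >= Fobs)) / (nPerm + 1),
                   n_perm = nPerm, seed = seed, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Sequential permutation tests of constrained axes
#'
#' Axis k is tested conditioning on axes 1..k-1: response and predictors are
#' residualized on the earlier axes' site scores, the first eigenvalue of
#' the reduced fit is the numerator, and rows of the residualized response
#' are permuted.  Testing proceeds forward and stops after the first axis
#' with p-value above \code{alpha} (axis tests are nested, so later axes
#' cannot be declared significant once an earlier one fails).
#'
#' @inheritParams testGlobal
#' @param alpha forward-stopping significance level (default 0.01)
#' @return data.frame with one row per tested axis (target = "axis:<k>");
#'   attribute \code{"sigAxes"} holds the indices of significant axes.
#'   See \code{\link{significantAxes}}.
#' @export
testAxes <- function(Y, X, nPerm = 1000L, seed = 1L, alpha = 0.01,
                     strata = NULL) {
    stopifnot(nPerm >= 1L)
    d <- .asYX(Y, X)
    n <- nrow(d$Y); p <- ncol(d$X)
    Yc <- .centerCols(d$Y)
    Xs <- .standardizeCols(d$X)
    model <- fitRDA(d$Y, d$X)
    dfr <- n - p - 1L
    denom <- model@unconstrainedInertia / dfr
    nAxes <- model@rank
    rows <- list()
    for (k in seq_len(nAxes)) {
        if (k == 1L) {
            Yr <- Yc; Xr <- Xs
        } else {
            Z <- model@sampleScores[, seq_len(k - 1L), drop = FALSE]
            Qz <- qr.Q(qr(Z))
            Yr <- Yc - Qz %*% crossprod(Qz, Yc)
            Xr <- Xs - Qz %*% crossprod(Qz, Xs)
        }
        Qx <- .projBasis(Xr)   # rank drops by k-1
        lam1 <- function(Ymat) {
            (svd(crossprod(Qx, Ymat), nu = 0, nv = 0)$d[1]^2) / (n - 1)
        }
        Fobs <- lam1(Yr) / denom
        set.seed(seed + 1000L + k)
        Fstar <- vapply(seq_len(nPerm), function(b)
            lam1(Yr[.permIndex(n, strata), , drop = FALSE]) / denom,
            numeric(1))
        pval <- (1 + sum(Fstar >= Fobs)) / (nPerm + 1)
        rows[[k]] <- data.frame(target = paste0("axis:", k), F = Fobs,
                                df_model = 1L, df_resid = dfr,
                                p_value = pval, n_perm = nPerm,
                                seed = seed, stringsAsFactors = FALSE)
        if (pval > alpha) break
    }
    res <- do.call(rbind, rows)
    attr(res, "sigAxes") <- which(res$p_value <= alpha)
    res
}

#' Significant axes from a testAxes result
#'
#' @param axisTests result of \code{\link{testAxes}}
#' @return integer vector of significant axis indices (possibly empty)
#' @export
significantAxes <- function(axisTests) {
    sig <- attr(axisTests, "sigAxes")
    if (is.null(sig)) sig <- which(axisTests$p_value <= 0.01)
    as.integer(sig)
}
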