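## Outlier-locus detection from extreme loadings on significant axes, and
## assignment of each outlier to its most correlated environmental
## predictor.  The karyotype pseudo-locus is scanned exactly like a SNP.

#' Detect outlier loci from axis loadings
#'
#' Per significant axis, flags loci whose loading lies strictly below the
#' empirical \code{tail} quantile or strictly above the \code{1 - tail}
#' quantile (order statistics with linear interpolation; ties at the
#' boundary are not flagged).  Loci flagged on several axes are deduplicated
#' to the axis of largest absolute loading; per-axis rows are kept in the
#' \code{"perAxis"} attribute.
#'
#' @param model an \linkS4class{RDAModel}
#' @param sigAxes integer indices of significant constrained axes
#' @param tail tail fraction per side (default 0.025)
#' @return data.frame (locus_id, axis, loading, tail, is_karyotype), one
#'   row per outlier locus
#' @export
detectOutliers <- function(model, sigAxes, tail = 0.025) {
    stopifnot(tail > 0, tail < 0.5, length(sigAxes) >= 1L)
    V <- model@locusScores
    if (nrow(V) < ceiling(1 / tail))
        warning("fewer than ", ceiling(1 / tail),
                " loci; tail quantiles are poorly resolved")
    rows <- lapply(sigAxes, function(ax) {
        v <- V[, ax]
        q <- stats::quantile(v, c(tail, 1 - tail), names = FALSE, type = 7)
        hit <- v < q[1] | v > q[2]
        if (!any(hit)) return(NULL)
        data.frame(locus_id = rownames(V)[hit], axis = ax,
                   loading = unname(v[hit]),
                   tail = ifelse(v[hit] < q[1], "lower", "upper"),
                   is_karyotype = model@isKaryotype[hit],
                   stringsAsFactors = FALSE)
    })
    perAxis <- do.call(rbind, rows)
    if (is.null(perAxis))
        perAxis <- data.frame(locus_id = character(), axis = integer(),
                              loading = numeric(), tail = character(),
                              is_karyotype = logical(),
                              stringsAsFactors = FALSE)
    ## deduplicate across axes: keep the max-|loading| row per locus
    ord <- order(perAxis$locus_id, -abs(perAxis$loading), perAxis$axis)
    dedup <- perAxis[ord, , drop = FALSE]
    dedup <- dedup[!duplicated(dedup$locus_id), , drop = FALSE]
    dedup <- dedup[order(match(dedup$locus_id, rownames(V))), , drop = FALSE]
    rownames(dedup) <- NULL
    attr(dedup, "perAxis") <- perAxis
    attr(dedup, "tail") <- tail
    dedup
}

#' Assign each outlier locus to its most correlated predictor
#'
#' best_predictor = argmax over retained predictors of |Pearson r| between
#' the (imputed) genotype column and the predictor; ties are broken
#' alphabetically (with a message).
#'
#' @param report outlier report from \code{\link{detectOutliers}}
#' @param Y complete \linkS4class{GenoExperiment} or samples x loci matrix
#'   used in the ordination (including the karyotype pseudo-locus)
#' @param X retained predictors (\linkS4class{PredictorSet} or matrix)
#' @return the report with \code{best_predictor} and \code{r_best} columns
#' @export
assignPredictors <- function(report, Y, X) {
    if (is(Y, "GenoExperiment")) Y <- genoMatrix(Y)
    Xm <- if (is(X, "PredictorSet")) predictorValues(X) else as.matrix(X)
    if (nrow(report) == 0L) {
        report$best_predictor <- character(0)
        report$r_best <- numeric(0)
        return(report)
    }
    miss <- setdiff(report$locus_id, colnames(Y))
    if (length(miss))
        stop("loci absent from genotype matrix: ",
             paste(miss, collapse = ", "))
    sub <- Y[, report$locus_id, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance locus column: ",
             paste(colnames(sub)[sds == 0], collapse = ", "))
    R <- abs(stats::cor(sub, Xm))
    pnames <- colnames(Xm)
    best <- character(nrow(R)); rbest <- numeric(nrow(R))
    for (i in seq_len(nrow(R))) {
        top <- which(R[i, ] >= max(R[i, ]) - 1e-12)
        if (length(top) > 1L)
            message("correlation tie for ", rownames(R)[i],
                    "; broken alphabetically")
        pick <- sort(pnames[top])[1L]
        best[i] <- pick
        rbest[i] <- stats::cor(sub[, i], Xm[, pick])
    }
    report$best_predictor <- best
    report$r_best <- rbest
    report
}

#' Karyotype pseudo-locus outlier status
#'
#' @param report outlier report (after \code{\link{detectOutliers}}, and
#'   typically \code{\link{assignPredictors}})
#' @return list: \code{flagged} (logical), plus \code{axis}, \code{loading},
#'   \code{tail}, \code{best_predictor}, \code{r_best} when flagged (NA
#'   otherwise)
#' @export
karyotypeStatus <- function(report) {
    if (!"is_karyotype" %in% colnames(report))
        stop("report lacks an is_karyotype column")
    i <- which(report$is_karyotype)
    if (length(i) == 0L)
        return(list(flagged = FALSE, axis = NA_integer_,
                    loading = NA_real_, tail = NA_character_,
                    best_predictor = NA_character_, r_best = NA_real_))
    i <- i[1L]
    list(flagged = TRUE, axis = report$axis[i],
         loading = report$loading[i], tail = report$tail[i],
         best_predictor = if ("best_predictor" %in% colnames(report))
             report$best_predictor[i] else NA_character_,
         r_best = if ("r_best" %in% colnames(report))
             report$r_best[i] else NA_real_)
}
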