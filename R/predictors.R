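## Environmental predictor reduction: complete-linkage clustering of
## 1 - |r| distances, one representative per cluster, plus a VIF check.

#' Pearson correlation matrix of a predictor set
#'
#' @param p a \linkS4class{PredictorSet} or numeric matrix (samples x
#'   predictors)
#' @return symmetric matrix of Pearson r with unit diagonal
#' @export
correlationMatrix <- function(p) {
    v <- if (is(p, "PredictorSet")) predictorValues(p) else as.matrix(p)
    stopifnot(ncol(v) >= 2L)
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance predictor: ",
             paste(colnames(v)[sds == 0], collapse = ", "))
    stats::cor(v)
}

## Cluster membership under complete linkage with *strict* merging: two
## predictors share a cluster iff they are joined by merges at height < cut.
## stats::hclust supplies the merge tree; membership is read off it directly
## because cutree() merges at height <= h.
.strictClusters <- function(D, cut) {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    n <- ncol(D)
    comp <- seq_len(n)                     # cluster id per leaf
    nodes <- vector("list", nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
        members <- unlist(lapply(hc$merge[k, ], function(j)
            if (j < 0) -j else nodes[[j]]))
        nodes[[k]] <- members
        if (hc$height[k] < cut)
            comp[members] <- min(comp[members])
    }
    unname(split(colnames(D), comp))
}

#' Reduce collinear predictors
#'
#' Clusters predictors by complete linkage on the distance 1 - |r| and cuts
#' the dendrogram at \code{cut} (default 0.3, i.e. merging predictors with
#' |r| > 0.7).  One representative is retained per cluster, chosen by (i)
#' class preference quarterly > monthly > other, (ii) lowest mean |r| with
#' predictors outside the cluster, (iii) input column order.  Complete
#' linkage guarantees all within-cluster distances are below the cut; it
#' does not guarantee every retained pair satisfies |r| <= 1 - cut when
#' chaining splits correlated predictors into different clusters.
#'
#' @param p a \linkS4class{PredictorSet}
#' @param cut dendrogram cut height in (0, 1); distance = 1 - |r|
#' @return a \linkS4class{PredictorReduction}
#' @export
reducePredictors <- function(p, cut = 0.3) {
    stopifnot(is(p, "PredictorSet"), cut > 0, cut < 1)
    r <- correlationMatrix(p)
    D <- 1 - abs(r)
    clusters <- .strictClusters(D, cut)
    pref <- c(quarterly = 1L, monthly = 2L, other = 3L)
    tags <- predictorClasses(p)
    order0 <- colnames(predictorValues(p))
    reps <- vapply(clusters, function(cl) {
        outside <- setdiff(order0, cl)
        meanOut <- if (length(outside))
            rowMeans(abs(r[cl, outside, drop = FALSE]))
        else
            stats::setNames(numeric(length(cl)), cl)
        ord <- order(pref[tags[cl]], meanOut[cl], match(cl, order0))
        cl[ord[1L]]
    }, character(1))
    retained <- order0[order0 %in% reps]
    new("PredictorReduction", retained = retained,
        clusters = unname(clusters), representatives = unname(reps),
        distance = D, correlation = r, cut = cut)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression of
#' predictor j on all other retained predictors.  Exact collinearity is
#' reported as an infinite VIF and fails the threshold.
#'
#' @param p a \linkS4class{PredictorSet} or numeric matrix
#' @param retained predictor names to check (default: all columns)
#' @param threshold pass criterion on the maximum VIF (default 10)
#' @return list with \code{vif} (named numeric), \code{pass} (logical) and
#'   \code{threshold}
#' @export
predictorVIF <- function(p, retained = NULL, threshold = 10) {
    v <- if (is(p, "PredictorSet")) predictorValues(p) else as.matrix(p)
    if (!is.null(retained)) v <- v[, retained, drop = FALSE]
    stopifnot(ncol(v) >= 2L)
    vs <- scale(v)
    out <- vapply(seq_len(ncol(vs)), function(j) {
        y <- vs[, j]
        X <- vs[, -j, drop = FALSE]
        fit <- stats::lm.fit(cbind(1, X), y)
        r2 <- 1 - sum(fit$residuals^2) / sum(y^2)
        if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    names(out) <- colnames(vs)
    list(vif = out, pass = all(is.finite(out)) && max(out) < threshold,
         threshold = threshold)
}

#' Build a PredictorSet aligned to a GenoExperiment
#'
#' Broadcasts a per-population predictor table to samples when needed and
#' reorders rows to the sample order of \code{g}.
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param table data.frame with either a \code{sample_id} or a
#'   \code{population} key column plus numeric predictor columns
#' @param classTag per-predictor class tags (see \code{\link{PredictorSet}})
#' @return a \linkS4class{PredictorSet} with one row per sample of \code{g}
#' @export
alignPredictors <- function(g, table, classTag = NULL) {
    if ("sample_id" %in% colnames(table)) {
        idx <- match(colnames(g), table$sample_id)
        key <- "sample_id"
    } else if ("population" %in% colnames(table)) {
        idx <- match(colData(g)$population, table$population)
        key <- "population"
    } else stop("predictor table needs a sample_id or population column")
    if (anyNA(idx)) stop("predictor table misses entries for some samples")
    vals <- as.matrix(table[idx, setdiff(colnames(table), key),
                            drop = FALSE])
    rownames(vals) <- colnames(g)
    PredictorSet(vals, classTag)
}

#' Subset a PredictorSet
#'
#' @param p a \linkS4class{PredictorSet}
#' @param samples sample ids (rows) to keep, in order; default all
#' @param predictors predictor names (columns) to keep; default all
#' @return a \linkS4class{PredictorSet}
#' @export
subsetPredictors <- function(p, samples = NULL, predictors = NULL) {
    v <- predictorValues(p)
    if (!is.null(samples)) v <- v[samples, , drop = FALSE]
    if (!is.null(predictors)) v <- v[, predictors, drop = FALSE]
    PredictorSet(v, predictorClasses(p)[colnames(v)])
}
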