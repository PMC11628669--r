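#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GenoExperiment: a genotype matrix with locus map and sample metadata
#'
#' Container for a samples x loci table of minor-allele counts (0/1/2, with
#' \code{NA} marking missing calls), stored Bioconductor-style as a
#' \linkS4class{SummarizedExperiment} with loci as rows and samples as
#' columns.  Row metadata carries the locus map (\code{contig},
#' \code{position}, 1-based) and an \code{is_karyotype} flag marking the
#' chromosome-number pseudo-locus appended by \code{\link{appendKaryotype}};
#' column metadata carries per-sample population, species, coordinates and
#' diploid chromosome number (\code{two_n}).
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the single
#'   assay is named \code{"geno"}.
#' @seealso \code{\link{readGenotypes}}, \code{\link{filterCoverage}},
#'   \code{\link{filterMAF}}, \code{\link{appendKaryotype}}
#' @exportClass GenoExperiment
setClass("GenoExperiment", contains = "SummarizedExperiment")

setValidity("GenoExperiment", function(object) {
    msg <- character()
    if (!"geno" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'geno' is required")
    rd <- rowData(object)
    for (col in c("contig", "position", "is_karyotype"))
        if (!col %in% colnames(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", col))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg) == 0L && "is_karyotype" %in% colnames(rd)) {
        snp <- !rd$is_karyotype
        v <- assay(object, "geno")[snp, , drop = FALSE]
        bad <- !is.na(v) & !(v %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, "SNP genotype entries must be 0, 1, 2 or NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenoExperiment
#'
#' @param geno integer matrix, samples x loci, entries in \{0, 1, 2, NA\}
#'   (minor-allele counts).  Row names are sample ids, column names locus ids;
#'   \code{locusMap$locus_id} / \code{samples$sample_id} are used when the
#'   matrix is unnamed.
#' @param locusMap data.frame with columns \code{locus_id}, \code{contig},
#'   \code{position} (1-based bp), one row per locus.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{population}, \code{species}, \code{latitude}, \code{longitude},
#'   \code{two_n} (diploid chromosome number; may be NA).
#' @param karyotypeRange integer length-2, declared bounds for valid 2n
#'   values (default \code{c(69, 84)}, the documented series for the study
#'   group).
#' @return a \linkS4class{GenoExperiment}
#' @export
GenoExperiment <- function(geno, locusMap, samples,
                           karyotypeRange = c(69L, 84L)) {
    stopifnot(is.matrix(geno))
    if (nrow(geno) == 0L)
        stop("empty input: zero samples")
    if (is.null(colnames(geno))) colnames(geno) <- locusMap$locus_id
    if (is.null(rownames(geno))) rownames(geno) <- samples$sample_id
    stopifnot(nrow(locusMap) == ncol(geno), nrow(samples) == nrow(geno))
    if (!all(samples$sample_id == rownames(geno)))
        samples <- samples[match(rownames(geno), samples$sample_id), ,
                           drop = FALSE]
    rd <- DataFrame(contig = as.character(locusMap$contig),
                    position = as.integer(locusMap$position),
                    is_karyotype = logical(nrow(locusMap)),
                    row.names = as.character(locusMap$locus_id))
    cd <- DataFrame(population = as.character(samples$population),
                    species = as.character(samples$species),
                    latitude = as.numeric(samples$latitude),
                    longitude = as.numeric(samples$longitude),
                    two_n = as.integer(samples$two_n),
                    row.names = as.character(samples$sample_id))
    se <- SummarizedExperiment(assays = list(geno = t(geno)),
                               rowData = rd, colData = cd)
    obj <- new("GenoExperiment", se)
    metadata(obj)$karyotypeRange <- as.integer(karyotypeRange)
    validObject(obj)
    obj
}

#' PredictorSet: per-sample environmental predictors
#'
#' Numeric predictor values (bioclim-style columns) aligned to the samples of
#' a \linkS4class{GenoExperiment}, with a per-column class tag used by the
#' variable-reduction step (quarterly summaries are preferred over monthly
#' ones when collapsing correlated clusters).
#'
#' @slot values numeric matrix, samples x predictors; no missing values.
#' @slot classTag named character, one of \code{"monthly"},
#'   \code{"quarterly"}, \code{"other"} per predictor.
#' @exportClass PredictorSet
setClass("PredictorSet",
         representation(values = "matrix", classTag = "character"))

setValidity("PredictorSet", function(object) {
    msg <- character()
    v <- object@values
    if (anyNA(v)) msg <- c(msg, "predictor values must be complete (no NA)")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "predictor names must be present and unique")
    if (!all(object@classTag %in% c("monthly", "quarterly", "other")))
        msg <- c(msg, "classTag entries must be monthly/quarterly/other")
    if (!identical(sort(names(object@classTag)), sort(colnames(v))))
        msg <- c(msg, "classTag must be named by the predictor columns")
    if (length(msg)) msg else TRUE
})

#' Construct a PredictorSet
#'
#' @param values numeric matrix or data.frame, samples x predictors, row
#'   names = sample ids.
#' @param classTag character vector of per-predictor class tags
#'   (\code{"monthly"}, \code{"quarterly"}, \code{"other"}); either named by
#'   predictor or in column order.  Defaults to \code{"other"} for all.
#' @return a \linkS4class{PredictorSet}
#' @export
PredictorSet <- function(values, classTag = NULL) {
    v <- as.matrix(values)
    storage.mode(v) <- "double"
    if (is.null(classTag))
        classTag <- rep("other", ncol(v))
    if (is.null(names(classTag))) {
        stopifnot(length(classTag) == ncol(v))
        names(classTag) <- colnames(v)
    }
    new("PredictorSet", values = v, classTag = classTag[colnames(v)])
}

#' PredictorReduction: result of collinearity-driven variable reduction
#'
#' @slot retained character, names of the representatives kept, in input
#'   column order.
#' @slot clusters list of character vectors, the predictor clusters found at
#'   the distance cut (distance = 1 - |r|, complete linkage).
#' @slot representatives character, one representative per cluster (parallel
#'   to \code{clusters}).
#' @slot distance matrix of 1 - |r| values.
#' @slot correlation matrix of Pearson r values.
#' @slot cut numeric, the dendrogram cut height.
#' @exportClass PredictorReduction
setClass("PredictorReduction",
         representation(retained = "character", clusters = "list",
                        representatives = "character", distance = "matrix",
                        correlation = "matrix", cut = "numeric"))

#' RDAModel: a fitted redundancy analysis
#'
#' Redundancy analysis of a complete genotype matrix Y (samples x loci,
#' column-centered) on standardized predictors X: least-squares fit
#' \eqn{\hat Y = X(X'X)^{-1}X'Y} followed by singular value decomposition of
#' \eqn{\hat Y}.  Constrained eigenvalues are \eqn{d_k^2/(n-1)}; inertia is
#' the summed column variance of Y (divisor n-1) and decomposes exactly into
#' constrained + unconstrained parts.
#'
#' @slot eig numeric, constrained eigenvalues (descending).
#' @slot eigResid numeric, unconstrained (residual) eigenvalues.
#' @slot totalInertia,constrainedInertia,unconstrainedInertia numeric scalars.
#' @slot pve numeric, per-axis proportion of constrained variance.
#' @slot locusScores L x k matrix, raw-eigenvector loadings ("species
#'   scores"); rows named by locus.
#' @slot sampleScores n x k matrix of site scores (linear-combination
#'   scores, per-axis variance equal to the eigenvalue).
#' @slot biplotScores p x k matrix, correlation of each predictor with each
#'   axis of sample scores.
#' @slot rank integer, number of constrained axes.
#' @slot nSamples,nPredictors integers.
#' @slot isKaryotype logical per locus; TRUE flags the chromosome-number
#'   pseudo-locus.
#' @exportClass RDAModel
setClass("RDAModel",
         representation(eig = "numeric", eigResid = "numeric",
                        totalInertia = "numeric",
                        constrainedInertia = "numeric",
                        unconstrainedInertia = "numeric",
                        pve = "numeric",
                        locusScores = "matrix", sampleScores = "matrix",
                        biplotScores = "matrix",
                        rank = "integer", nSamples = "integer",
                        nPredictors = "integer",
                        isKaryotype = "logical"))

setValidity("RDAModel", function(object) {
    msg <- character()
    if (any(object@eig < -1e-10))
        msg <- c(msg, "constrained eigenvalues must be nonnegative")
    if (is.unsorted(rev(object@eig), strictly = FALSE) &&
        length(object@eig) > 1L)
        msg <- c(msg, "constrained eigenvalues must be descending")
    tot <- object@constrainedInertia + object@unconstrainedInertia
    if (abs(tot - object@totalInertia) >
        1e-8 * max(1, abs(object@totalInertia)))
        msg <- c(msg, "inertia decomposition must sum to total inertia")
    if (length(msg)) msg else TRUE
})
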