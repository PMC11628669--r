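#' Accessors for GenoExperiment and friends
#'
#' \code{genoMatrix} returns the samples x loci numeric matrix (the analysis
#' orientation); \code{locusMap} the per-locus map (locus_id, contig,
#' position, is_karyotype); \code{sampleData} the per-sample metadata;
#' \code{isKaryotype} the per-locus pseudo-locus flag;
#' \code{karyotypeIndex} the column index of the karyotype pseudo-locus in
#' \code{genoMatrix} (NA when absent).
#'
#' @param x a \linkS4class{GenoExperiment} (or \linkS4class{PredictorSet} /
#'   \linkS4class{RDAModel} where documented)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @rdname accessors
#' @export
setGeneric("locusMap", function(x) standardGeneric("locusMap"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("isKaryotype", function(x) standardGeneric("isKaryotype"))

#' @rdname accessors
#' @export
setGeneric("karyotypeIndex", function(x) standardGeneric("karyotypeIndex"))

#' @rdname accessors
#' @export
setGeneric("predictorValues", function(x) standardGeneric("predictorValues"))

#' @rdname accessors
#' @export
setGeneric("predictorClasses",
           function(x) standardGeneric("predictorClasses"))

#' RDAModel accessors
#'
#' @param x an \linkS4class{RDAModel}
#' @name rda-accessors
NULL

#' @rdname rda-accessors
#' @export
setGeneric("eigenvaluesConstrained",
           function(x) standardGeneric("eigenvaluesConstrained"))

#' @rdname rda-accessors
#' @export
setGeneric("eigenvaluesUnconstrained",
           function(x) standardGeneric("eigenvaluesUnconstrained"))

#' @rdname rda-accessors
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @rdname rda-accessors
#' @export
setGeneric("locusScores", function(x) standardGeneric("locusScores"))

#' @rdname rda-accessors
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname rda-accessors
#' @export
setGeneric("biplotScores", function(x) standardGeneric("biplotScores"))

#' @rdname rda-accessors
#' @export
setGeneric("pve", function(x) standardGeneric("pve"))
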