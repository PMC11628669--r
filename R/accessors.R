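#' @rdname accessors
#' @export
setMethod("genoMatrix", "GenoExperiment", function(x) {
    t(assay(x, "geno"))
})

#' @rdname accessors
#' @export
setMethod("locusMap", "GenoExperiment", function(x) {
    rd <- rowData(x)
    data.frame(locus_id = rownames(x),
               contig = rd$contig,
               position = rd$position,
               is_karyotype = rd$is_karyotype,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("sampleData", "GenoExperiment", function(x) {
    cd <- colData(x)
    data.frame(sample_id = rownames(cd), as.data.frame(cd),
               stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("isKaryotype", "GenoExperiment", function(x) {
    structure(rowData(x)$is_karyotype, names = rownames(x))
})

#' @rdname accessors
#' @export
setMethod("karyotypeIndex", "GenoExperiment", function(x) {
    i <- which(rowData(x)$is_karyotype)
    if (length(i) == 0L) NA_integer_ else i[1L]
})

#' @rdname accessors
#' @export
setMethod("predictorValues", "PredictorSet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("predictorClasses", "PredictorSet", function(x) x@classTag)

setMethod("show", "GenoExperiment", function(object) {
    nk <- sum(rowData(object)$is_karyotype)
    cat(sprintf(
        "GenoExperiment: %d samples x %d loci (%d SNP, %d karyotype)\n",
        ncol(object), nrow(object), nrow(object) - nk, nk))
    cat(sprintf("  populations: %d | missing calls: %.2f%%\n",
                length(unique(colData(object)$population)),
                100 * mean(is.na(assay(object, "geno")))))
    invisible(NULL)
})

setMethod("show", "PredictorSet", function(object) {
    cat(sprintf("PredictorSet: %d samples x %d predictors\n",
                nrow(object@values), ncol(object@values)))
    tab <- table(object@classTag)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    invisible(NULL)
})

setMethod("show", "PredictorReduction", function(object) {
    cat(sprintf("PredictorReduction: %d -> %d predictors (cut = %g)\n",
                ncol(object@distance), length(object@retained), object@cut))
    for (i in seq_along(object@clusters)) {
        cl <- object@clusters[[i]]
        cat(sprintf("  [%s] %s\n", object@representatives[i],
                    paste(cl, collapse = ", ")))
    }
    invisible(NULL)
})

#' @rdname rda-accessors
#' @export
setMethod("eigenvaluesConstrained", "RDAModel", function(x) x@eig)

#' @rdname rda-accessors
#' @export
setMethod("eigenvaluesUnconstrained", "RDAModel", function(x) x@eigResid)

#' @rdname rda-accessors
#' @export
setMethod("inertia", "RDAModel", function(x) {
    c(total = x@totalInertia, constrained = x@constrainedInertia,
      unconstrained = x@unconstrainedInertia)
})

#' @rdname rda-accessors
#' @export
setMethod("locusScores", "RDAModel", function(x) x@locusScores)

#' @rdname rda-accessors
#' @export
setMethod("sampleScores", "RDAModel", function(x) x@sampleScores)

#' @rdname rda-accessors
#' @export
setMethod("biplotScores", "RDAModel", function(x) x@biplotScores)

#' @rdname rda-accessors
#' @export
setMethod("pve", "RDAModel", function(x) x@pve)

setMethod("show", "RDAModel", function(object) {
    cat(sprintf("RDAModel: %d samples, %d loci, %d predictors\n",
                object@nSamples, nrow(object@locusScores),
                object@nPredictors))
    cat(sprintf("  inertia: total %.4f = constrained %.4f (%.1f%%) + unconstrained %.4f\n",
                object@totalInertia, object@constrainedInertia,
                100 * object@constrainedInertia / object@totalInertia,
                object@unconstrainedInertia))
    k <- min(4L, length(object@eig))
    cat("  constrained eigenvalues:",
        paste(sprintf("%.4f", object@eig[seq_len(k)]), collapse = ", "),
        if (length(object@eig) > k) "..." else "", "\n")
    cat("  PVE:",
        paste(sprintf("%.3f", object@pve[seq_len(k)]), collapse = ", "),
        "\n")
    invisible(NULL)
})
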