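## End-to-end orchestration: filters -> (optional cytotype subsample) ->
## imputation -> (optional karyotype append) -> predictor reduction + VIF ->
## RDA -> permutation tests -> outlier scan -> (optional annotation).
## All thresholds default to the protocol values this pipeline reproduces:
## coverage >= 100 called samples, MAF >= 0.10, correlation-cluster cut 0.3,
## VIF < 10, 1000 permutations, alpha 0.01, 2.5% loading tails, 50 kbp gene
## window.

#' Run the full genotype-environment association pipeline
#'
#' @param geno a \linkS4class{GenoExperiment} (missing calls allowed)
#' @param predictors a per-sample \linkS4class{PredictorSet}
#' @param variant analysis variant: \code{"with_karyotype"} (default),
#'   \code{"without_karyotype"}, or \code{"cytotype_subsample"} (one sample
#'   per (population, 2n) pair, karyotype included)
#' @param minCalled coverage threshold (default 100)
#' @param mafMin MAF threshold (default 0.10)
#' @param cut predictor-cluster distance cut (default 0.3)
#' @param vifThreshold VIF pass bound (default 10)
#' @param nPerm permutations per test (default 1000)
#' @param alpha axis significance level (default 0.01)
#' @param tail outlier tail fraction per side (default 0.025)
#' @param window annotation window in bp (default 50000)
#' @param seed integer seed driving the subsample and all permutations
#' @param genes optional \linkS4class{GRanges} from
#'   \code{\link{readAnnotation}}; outliers are annotated when supplied
#' @param karyotypeScaling passed to \code{\link{appendKaryotype}}
#' @param strata optional permutation strata (e.g. \code{"population"} to
#'   permute within populations)
#' @return list of class \code{"rdaRun"}: the fitted model, test tables,
#'   outlier report, karyotype status, and a serializable \code{report}
#'   summary (filter counts, retained predictors, inertia, PVE, significant
#'   axes, outlier counts per predictor, seed)
#' @export
runPipeline <- function(geno, predictors,
                        variant = c("with_karyotype", "without_karyotype",
                                    "cytotype_subsample"),
                        minCalled = 100L, mafMin = 0.10, cut = 0.3,
                        vifThreshold = 10, nPerm = 1000L, alpha = 0.01,
                        tail = 0.025, window = 50000L, seed = 1L,
                        genes = NULL,
                        karyotypeScaling = c("standardized", "raw"),
                        strata = NULL) {
    variant <- match.arg(variant)
    karyotypeScaling <- match.arg(karyotypeScaling)
    t0 <- Sys.time()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    lociIn <- nrow(geno)
    g <- stage("filter_coverage", filterCoverage(geno, minCalled))
    lociCov <- nrow(g)
    g <- stage("filter_maf", filterMAF(g, mafMin))
    lociMAF <- nrow(g)
    if (lociMAF == 0L) stop("no loci survive filtering")

    if (variant == "cytotype_subsample")
        g <- stage("cytotype_subsample",
                   subsampleOnePerCytotype(g, seed = seed))

    g <- stage("impute", imputeMissing(g))
    if (variant != "without_karyotype")
        g <- stage("append_karyotype",
                   appendKaryotype(g, scaling = karyotypeScaling))

    p <- stage("align_predictors",
               subsetPredictors(predictors, samples = colnames(g)))
    red <- stage("reduce_predictors", reducePredictors(p, cut = cut))
    pKeep <- subsetPredictors(p, predictors = red@retained)
    vifRes <- stage("vif", predictorVIF(pKeep, threshold = vifThreshold))

    strataVec <- if (identical(strata, "population"))
        colData(g)$population else strata

    model <- stage("fit_rda", fitRDA(g, pKeep))
    Y <- genoMatrix(g); Xv <- predictorValues(pKeep)
    globalTest <- stage("test_global",
                        testGlobal(Y, Xv, nPerm = nPerm, seed = seed,
                                   strata = strataVec))
    termTests <- stage("test_terms",
                       testTerms(Y, Xv, nPerm = nPerm, seed = seed,
                                 strata = strataVec))
    axisTests <- stage("test_axes",
                       testAxes(Y, Xv, nPerm = nPerm, seed = seed,
                                alpha = alpha, strata = strataVec))
    sigAxes <- significantAxes(axisTests)

    if (length(sigAxes)) {
        outliers <- stage("detect_outliers",
                          detectOutliers(model, sigAxes, tail = tail))
        outliers <- stage("assign_predictors",
                          assignPredictors(outliers, g, pKeep))
    } else {
        outliers <- data.frame(locus_id = character(), axis = integer(),
                               loading = numeric(), tail = character(),
                               is_karyotype = logical(),
                               best_predictor = character(),
                               r_best = numeric(), stringsAsFactors = FALSE)
    }
    karyo <- if (variant == "without_karyotype") {
        list(flagged = FALSE, axis = NA_integer_, loading = NA_real_,
             tail = NA_character_, best_predictor = NA_character_,
             r_best = NA_real_)
    } else karyotypeStatus(outliers)

    annotated <- if (!is.null(genes) && nrow(outliers))
        stage("annotate", annotateOutliers(outliers, locusMap(g), genes,
                                           window = window))
    else NULL

    perPredictor <- if (nrow(outliers))
        as.list(table(outliers$best_predictor)) else list()
    report <- list(
        variant = variant,
        n_samples = ncol(g), n_populations =
            length(unique(colData(g)$population)),
        loci_in = lociIn, loci_after_coverage = lociCov,
        loci_after_maf = lociMAF,
        retained_predictors = red@retained,
        vif = as.list(vifRes$vif), vif_pass = vifRes$pass,
        total_inertia = model@totalInertia,
        constrained_inertia = model@constrainedInertia,
        constrained_pct = 100 * model@constrainedInertia /
            model@totalInertia,
        eigenvalues = model@eig, pve = model@pve,
        global_p = globalTest$p_value,
        term_p = stats::setNames(as.list(termTests$p_value),
                                 sub("^term:", "", termTests$target)),
        significant_axes = sigAxes,
        n_outliers = nrow(outliers),
        n_outliers_snp = sum(!outliers$is_karyotype),
        outliers_per_predictor = perPredictor,
        karyotype = karyo,
        seed = seed, n_perm = nPerm, alpha = alpha, tail = tail,
        thresholds = list(min_called = minCalled, maf_min = mafMin,
                          cut = cut, vif = vifThreshold,
                          window = window),
        runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    structure(list(geno = g, predictors = pKeep, reduction = red,
                   model = model, global_test = globalTest,
                   term_tests = termTests, axis_tests = axisTests,
                   outliers = outliers, annotated = annotated,
                   karyotype_status = karyo, report = report),
              class = "rdaRun")
}

#' @export
print.rdaRun <- function(x, ...) {
    r <- x$report
    cat(sprintf("rdaRun (%s): %d samples, %d -> %d loci\n", r$variant,
                r$n_samples, r$loci_in, r$loci_after_maf))
    cat(sprintf("  constrained inertia: %.1f%% | global p = %.4g\n",
                r$constrained_pct, r$global_p))
    cat(sprintf("  significant axes: %s | outliers: %d (karyotype %s)\n",
                if (length(r$significant_axes))
                    paste(r$significant_axes, collapse = ",") else "none",
                r$n_outliers,
                if (isTRUE(r$karyotype$flagged)) "flagged" else "not flagged"))
    invisible(x)
}

#' Serialize / reload a run report
#'
#' The summary block of an \code{\link{runPipeline}} result round-trips
#' losslessly through JSON (the \code{runtime_sec} field is excluded from
#' equality expectations by callers since it is wall-clock).
#'
#' @param run an \code{"rdaRun"} object (or its \code{$report})
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeRunReport <- function(run, path) {
    report <- if (inherits(run, "rdaRun")) run$report else run
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

#' @rdname writeRunReport
#' @export
readRunReport <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
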