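## Synthetic landscape-genomics data with known ground truth.
##
## Population structure follows the Balding-Nichols model: per-population
## allele frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around an ancestral
## frequency p ~ Uniform(mafFloor, 1 - mafFloor), with F the baseline
## differentiation (FST).  Environment-associated loci instead take
## population frequency logistic(logit(p) + beta * z), with z the
## standardized linked predictor at the population.  The karyotype is an
## integer trait 2n = round(base + slope * z + within-population noise)
## clipped to its declared range.  Predictors are built from four latent
## latitudinal gradients, each observed as a correlated pair (quarterly +
## monthly/other variant) so the reduction step has structure to collapse.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: 34 populations,
#' unbalanced sampling (sizes clipped to 1..17, median about 3, total about
#' 150 samples), roughly 700 biallelic SNPs of which 50 carry an
#' environmental association, a chromosome-number series on 69-84 with a
#' minimum-temperature cline and within-population dispersion, and
#' bioclim-style predictors arriving in collinear clusters.
#'
#' @param nPops number of populations (default 34)
#' @param nNeutral,nAdaptive neutral / environment-associated SNP counts
#'   (defaults 650 / 50)
#' @param fst baseline differentiation in (0, 1) (default 0.15)
#' @param beta effect size on the logit population allele frequency per SD
#'   of the linked predictor (default 1.5)
#' @param karyotypeSlope chromosomes per SD of the karyotype-linked
#'   predictor (default 2.5); 0 gives an environment-independent karyotype
#' @param karyotypeSD within-population karyotype dispersion (default 1.5)
#' @param karyotypeBase centre of the 2n series (default 76.5)
#' @param karyotypeRange valid 2n bounds (default c(69, 84))
#' @param karyotypePredictor name of the predictor driving the karyotype
#'   cline (default "BIO6")
#' @param missingRate per-cell genotype missingness (default 0.05)
#' @param mafFloor lower bound of the ancestral allele frequency, in
#'   (0, 0.5) (default 0.10)
#' @param linkedPredictors predictors the adaptive loci cycle through
#'   (default the four cluster representatives BIO4/BIO6/BIO16/BIO17)
#' @param popSizes optional fixed per-population sample sizes (scalar or
#'   length \code{nPops}); \code{NULL} (default) draws unbalanced sizes
#'   matching the study's sampling quartiles
#' @param seed integer seed
#' @return a list of class \code{"SimConfig"}
#' @export
simConfig <- function(nPops = 34L, nNeutral = 650L, nAdaptive = 50L,
                      fst = 0.15, beta = 1.5, karyotypeSlope = 2.5,
                      karyotypeSD = 1.5, karyotypeBase = 76.5,
                      karyotypeRange = c(69L, 84L),
                      karyotypePredictor = "BIO6",
                      missingRate = 0.05, mafFloor = 0.10,
                      linkedPredictors = c("BIO6", "BIO16", "BIO17",
                                           "BIO4"),
                      popSizes = NULL, seed = 1L) {
    stopifnot(nPops >= 2L, nNeutral >= 0L, nAdaptive >= 0L,
              fst > 0, fst < 1, missingRate >= 0, missingRate < 1)
    if (mafFloor <= 0 || mafFloor >= 0.5)
        stop("mafFloor must lie in (0, 0.5)")
    if (karyotypeRange[1] >= karyotypeRange[2])
        stop("karyotypeRange must be ordered")
    structure(list(nPops = nPops, nNeutral = nNeutral,
                   nAdaptive = nAdaptive, fst = fst, beta = beta,
                   karyotypeSlope = karyotypeSlope,
                   karyotypeSD = karyotypeSD,
                   karyotypeBase = karyotypeBase,
                   karyotypeRange = karyotypeRange,
                   karyotypePredictor = karyotypePredictor,
                   missingRate = missingRate, mafFloor = mafFloor,
                   linkedPredictors = linkedPredictors,
                   popSizes = popSizes, seed = seed),
              class = "SimConfig")
}

## Latent environmental gradients and their observed bioclim-style
## realisations.  Returns per-population predictor values plus class tags.
.simPredictors <- function(nPops, lat) {
    latz <- as.numeric(scale(lat))
    z6  <- as.numeric(scale(-0.7 * latz + sqrt(0.51) * stats::rnorm(nPops)))
    z4  <- as.numeric(scale(0.4 * latz + stats::rnorm(nPops)))
    z16 <- as.numeric(scale(0.3 * latz + stats::rnorm(nPops)))
    z17 <- as.numeric(scale(-0.3 * latz + stats::rnorm(nPops)))
    obs <- function(z, sd = 0.2) z + stats::rnorm(nPops, sd = sd)
    vals <- cbind(BIO4 = z4, BIO7 = obs(z4),
                  BIO6 = z6, BIO1 = obs(z6),
                  BIO16 = z16, BIO13 = obs(z16),
                  BIO17 = z17, BIO14 = obs(z17))
    tags <- c(BIO4 = "other", BIO7 = "other",
              BIO6 = "monthly", BIO1 = "other",
              BIO16 = "quarterly", BIO13 = "monthly",
              BIO17 = "quarterly", BIO14 = "monthly")
    list(values = vals, tags = tags)
}

#' Simulate a landscape-genomics dataset
#'
#' @param config a \code{\link{simConfig}} list
#' @return list with \code{geno} (a \linkS4class{GenoExperiment}; SNPs only,
#'   missing calls included), \code{predictors} (a per-sample
#'   \linkS4class{PredictorSet}), \code{truth} (per-locus class, linked
#'   predictor and effect size, including a row for the karyotype), and
#'   \code{config}
#' @export
simulateLandscape <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    nPops <- config$nPops

    ## unbalanced sampling: sizes in 1..17, median ~3, total ~4.4 * nPops
    sizes <- if (is.null(config$popSizes))
        pmin(1L + stats::rnbinom(nPops, size = 1.2, mu = 3.4), 17L)
    else
        as.integer(rep_len(config$popSizes, nPops))
    nSamp <- sum(sizes)
    popOf <- rep(seq_len(nPops), sizes)
    popIds <- sprintf("P%02d", seq_len(nPops))
    sampleIds <- paste0(popIds[popOf], "_",
                        unlist(lapply(sizes, seq_len)))

    lat <- sort(stats::runif(nPops, 31, 55))      # south-to-north gradient
    lon <- stats::runif(nPops, -10, 5)
    env <- .simPredictors(nPops, lat)

    ## per-sample predictor values (population climate broadcast)
    predVals <- env$values[popOf, , drop = FALSE]
    rownames(predVals) <- sampleIds

    ## standardized (over samples) predictor used to drive clines
    zOf <- function(name) as.numeric(scale(predVals[, name]))

    nLoci <- config$nNeutral + config$nAdaptive
    lociIds <- sprintf("SNP%04d", seq_len(nLoci))
    classes <- rep(c("neutral", "adaptive"),
                   c(config$nNeutral, config$nAdaptive))
    linked <- rep(NA_character_, nLoci)
    betas <- rep(0, nLoci)
    if (config$nAdaptive > 0) {
        idx <- which(classes == "adaptive")
        linked[idx] <- rep(config$linkedPredictors,
                           length.out = config$nAdaptive)
        betas[idx] <- config$beta * sample(c(-1, 1), config$nAdaptive,
                                           replace = TRUE)
    }

    p0 <- stats::runif(nLoci, config$mafFloor, 1 - config$mafFloor)
    F <- config$fst
    geno <- matrix(NA_integer_, nSamp, nLoci,
                   dimnames = list(sampleIds, lociIds))
    popZ <- lapply(stats::setNames(nm = config$linkedPredictors),
                   function(nm) as.numeric(scale(env$values[, nm])))
    for (l in seq_len(nLoci)) {
        if (classes[l] == "neutral") {
            pf <- stats::rbeta(nPops, p0[l] * (1 - F) / F,
                               (1 - p0[l]) * (1 - F) / F)
        } else {
            pf <- stats::plogis(stats::qlogis(p0[l]) +
                                    betas[l] * popZ[[linked[l]]])
        }
        geno[, l] <- stats::rbinom(nSamp, 2L, pf[popOf])
    }

    ## karyotype: cline on the linked predictor + within-population noise
    zk <- zOf(config$karyotypePredictor)
    twoN <- round(config$karyotypeBase + config$karyotypeSlope * zk +
                      stats::rnorm(nSamp, sd = config$karyotypeSD))
    twoN <- pmin(pmax(twoN, config$karyotypeRange[1]),
                 config$karyotypeRange[2])

    if (config$missingRate > 0) {
        drop <- stats::runif(length(geno)) < config$missingRate
        geno[drop] <- NA_integer_
    }

    samples <- data.frame(sample_id = sampleIds,
                          population = popIds[popOf],
                          species = ifelse(lat[popOf] < 38, "southern",
                                           "northern"),
                          latitude = lat[popOf] +
                              stats::rnorm(nSamp, sd = 0.05),
                          longitude = lon[popOf], two_n = as.integer(twoN),
                          stringsAsFactors = FALSE)
    lmap <- data.frame(locus_id = lociIds,
                       contig = sprintf("ctg%02d",
                                        (seq_len(nLoci) - 1L) %% 20L + 1L),
                       position = 1000L + 5000L * ((seq_len(nLoci) - 1L)
                                                   %/% 20L),
                       stringsAsFactors = FALSE)
    truth <- data.frame(locus_id = c(lociIds, "KARYOTYPE"),
                        class = c(classes, "karyotype"),
                        linked_predictor = c(linked,
                            if (config$karyotypeSlope != 0)
                                config$karyotypePredictor
                            else NA_character_),
                        beta = c(betas, config$karyotypeSlope),
                        stringsAsFactors = FALSE)
    list(geno = GenoExperiment(geno, lmap, samples,
                               karyotypeRange = config$karyotypeRange),
         predictors = PredictorSet(predVals, env$tags),
         truth = truth, config = config)
}

#' Score an outlier report against simulation truth
#'
#' TPR = flagged adaptive loci / all adaptive loci; FDR = flagged neutral
#' loci / all flagged SNP loci (0, with \code{fdr_defined = FALSE}, when
#' nothing is flagged).  The karyotype pseudo-locus is scored separately.
#'
#' @param report outlier report (see \code{\link{detectOutliers}})
#' @param truth truth table from \code{\link{simulateLandscape}}
#' @return list: tpr, fdr, fdr_defined, karyotype_detected, n_flagged
#' @export
evaluateDetection <- function(report, truth) {
    unknown <- setdiff(report$locus_id, truth$locus_id)
    if (length(unknown))
        stop("loci absent from truth table: ",
             paste(unknown, collapse = ", "))
    cls <- truth$class[match(report$locus_id, truth$locus_id)]
    nAdaptive <- sum(truth$class == "adaptive")
    flaggedSNP <- sum(cls != "karyotype")
    tpr <- if (nAdaptive > 0) sum(cls == "adaptive") / nAdaptive else NA_real_
    fdr <- if (flaggedSNP > 0) sum(cls == "neutral") / flaggedSNP else 0
    list(tpr = tpr, fdr = fdr, fdr_defined = flaggedSNP > 0,
         karyotype_detected = any(cls == "karyotype"),
         n_flagged = nrow(report))
}
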