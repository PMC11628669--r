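Package: karyoRDA
Title: Karyotype-Aware Redundancy Analysis for Genotype-Environment
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landscape-genomics toolkit for detecting environment-associated
    loci by redundancy analysis (RDA), with the diploid chromosome number
    treated as an additional pseudo-locus so that karyotype variation can be
    scanned alongside SNPs. Provides genotype import and filtering (coverage,
    minor allele frequency), collinearity-driven reduction of bioclimatic
    predictors by complete-linkage correlation clustering with a variance
    inflation factor check, a from-scratch constrained-ordination engine with
    permutation tests for the global model, individual predictors and
    ordination axes, tail-based outlier-locus detection with assignment of
    each outlier to its most correlated predictor, gene-window annotation
    against a GFF3 reference, and a population-genetic simulator
    (Balding-Nichols differentiation plus logistic allele-frequency clines
    and a karyotype cline) for power and false-discovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
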