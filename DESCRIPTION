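Package: chromCompare
Title: Group-Wise Comparison of Chromatin-State Segmentations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects genes whose chromatin-state annotation systematically
    differs between two groups of epigenomes. Each epigenome is encoded as
    per-gene chromatin-state coverage fractions over gene bodies; every
    (gene, state) feature is corrected for external covariates (donor sex,
    processing lab, sample type, solid/liquid state) using deviance residuals
    from a per-feature binomial logistic regression that excludes the tested
    property; corrected features are compared between groups with rank-based
    or parametric tests under multiple-testing control. Downstream utilities
    cover gene-set enrichment with Storey q-values, differential expression
    of distinguishing genes, odds-ratio analysis linking epigenomic and
    transcriptional differences, heatmap matrix construction with
    mean-ordered clustering, label-shuffling null calibration, and a fully
    synthetic cohort generator with planted effects for validation.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, ChromatinState, StatisticalMethod, GeneSetEnrichment
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'chromCompare-package.R'
    'io-metadata.R'
    'palette.R'
    'io-segmentation.R'
    'features.R'
    'covariates.R'
    'comparison.R'
    'enrichment.R'
    'expression-analysis.R'
    'io-expression.R'
    'io-genes.R'
    'io-gmt.R'
    'randomization.R'
    'structure.R'
    'pipeline.R'
    'synthetic.R'
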