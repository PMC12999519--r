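Package: convorg
Title: Developmental Convergence Analysis for Multi-Form Cortical Organoid Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting developmental transcriptomic
    convergence across genetic forms of a disorder in cortical organoid
    cohorts and for inferring upstream regulator modules. Implements
    expression filtering and TMM normalization, sample-network outlier
    removal, per-gene mixed-model differential expression with fixed-effect
    meta-analysis across forms, logFC clustering with multiscale bootstrap
    support, per-day cross-form convergence statistics, robust form-balanced
    consensus signed co-expression networks (median of resampled topological
    overlap), module eigengenes and kME, a kME-weighted module-to-module
    regulation score, Fisher and specificity-bootstrap enrichment, bulk
    deconvolution with adjusted-logit proportion tests, a permutation
    connectedness test for IP-MS bait-prey networks, and CROP-seq style
    gRNA assignment with pseudobulk differential expression. Includes
    synthetic-data generators that emulate the cohort structure with a
    full ground-truth record for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    edgeR,
    limma,
    lme4,
    pracma,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
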