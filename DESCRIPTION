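Package: methvar
Title: Hierarchical Beta-Binomial Modeling of Single-Cell DNA Methylation Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cell-to-cell DNA methylation heterogeneity from sparse
    single-cell bisulphite sequencing data. Feature-level methylated/covered
    CpG counts are modeled with a hierarchical beta-binomial model in which
    mean methylation depends on feature covariates (e.g. CpG density) through
    a logit-linear regression and overdispersion follows a radial-basis
    regression on the mean. Feature-specific residual overdispersion -- the
    deviation of logit overdispersion from the mean-driven trend -- is the
    variability measure used for highly-variable-feature selection and for
    differential mean/variability testing between cell groups, with decision
    rules based on posterior tail probabilities calibrated to control the
    expected false discovery rate. Includes a synthetic-data generator,
    per-feature beta-binomial maximum-likelihood and variance-based baseline
    methods, and genomic utilities to aggregate per-CpG calls into feature
    counts over windows, promoters or BED intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
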