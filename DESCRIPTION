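Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipelines on GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal inference from GWAS summary statistics:
    instrument selection and quality control (p-value thresholding, LD
    clumping, variance explained and F-statistics), two-sample Mendelian
    randomization estimators (inverse-variance weighted, MR-Egger, weighted
    median) with heterogeneity, pleiotropy and leave-one-out sensitivity
    analyses, Benjamini-Hochberg FDR tiering, fixed-effects meta-analysis
    across cohorts, multivariable MR with lasso exposure selection, two-step
    MR protein mediation with delta-method standard errors, Bayesian
    colocalization via approximate Bayes factors, and transcriptome-wide
    association overlap with Fisher-combined p-values. Includes seeded
    generators of synthetic summary statistics with recorded ground truth
    for end-to-end validation, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
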