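Package: summarymr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates causal effects from paired GWAS summary statistics
    using the two-sample Mendelian randomization framework: harmonization of
    exposure and outcome associations onto a shared effect allele, LD-based
    instrument pruning and proxy substitution, per-variant Wald ratios pooled
    by fixed-effects inverse-variance weighting, MR-Egger regression for
    directional pleiotropy, the weighted-median estimator with parametric
    bootstrap, Cochran's Q / I-squared heterogeneity with test-based
    confidence intervals, declarative sensitivity analyses, a bidirectional
    mode, and a calibrated generator of synthetic summary statistics with
    known ground truth. Ships a transcription of published summary statistics
    for 70 body-mass-index instruments and their multiple sclerosis
    associations (GIANT and IMSGC consortia) as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pracma,
    ggplot2,
    optparse
Config/testthat/edition: 3
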