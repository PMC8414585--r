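Package: gwasmr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) with GWAS summary
    statistics: instrument selection at a genome-wide significance
    threshold, allele harmonization across exposure and outcome studies
    (including palindromic-variant handling), per-variant Wald ratios,
    fixed-effect inverse-variance weighted (IVW) estimation, an
    LD-adjusted generalized-least-squares IVW for correlated instruments,
    MR-Egger regression with its pleiotropy intercept test, the weighted
    median estimator with a parametric-bootstrap standard error,
    Cochran's Q / I-squared heterogeneity statistics, leave-one-out
    sensitivity analysis, binary-outcome power calculations
    (detectable odds-ratio bounds), and a seeded synthetic
    summary-statistic generator with known causal effect and pleiotropy
    structure so every pipeline stage can be validated without external
    data. A plan-driven pipeline orchestrates bidirectional analyses
    across exposure-outcome pairs with Bonferroni correction and emits
    tidy report tables for forest, scatter, and leave-one-out displays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
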