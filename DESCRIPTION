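Package: mrscreen
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument screening, allele harmonization and causal-effect
    estimation for two-sample Mendelian randomization on GWAS summary
    statistics. Implements the Wald ratio, fixed and multiplicative
    random-effects inverse-variance-weighted (IVW) estimators, MR-Egger
    regression with its intercept-based pleiotropy test, the weighted-median
    estimator with bootstrap standard errors, Cochran Q and Rucker Q'
    heterogeneity statistics, the MR-PRESSO global, outlier and distortion
    tests, leave-one-out sensitivity analysis, funnel-plot tables,
    instrument-strength F statistics and a binary-outcome power calculation.
    Ships the 63-variant leisure-screen-time / diabetic-retinopathy
    instrument table as package data and a synthetic summary-statistics
    generator with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
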