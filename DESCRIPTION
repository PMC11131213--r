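Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of
    many exposures (for example blood metabolites) against many outcomes
    (disease risk or quantitative traits) from GWAS summary statistics.
    Covers instrument selection (p-value screen, greedy LD clumping,
    per-variant variance explained and F statistics, weak-instrument
    removal), allele harmonization with palindromic-variant removal,
    Steiger directionality filtering, the inverse-variance weighted,
    MR-Egger and weighted-median causal estimators, sensitivity
    diagnostics (Cochran's Q, MR-Egger intercept, a simulation-based
    residual-sum-of-squares global pleiotropy test, leave-one-out), a
    two-tier Bonferroni/nominal significance classification for screens,
    and a calibrated generator of paired synthetic exposure/outcome
    summary statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
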