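Package: gwasmr
Title: Two-Sample and Multivariable Mendelian Randomisation from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) from GWAS
    summary statistics: reading, validating and combining association
    tables (including fixed-effects inverse-variance meta-analysis of
    correlated endpoints with LD-score-intercept standard-error
    inflation); instrument selection, LD clumping, allele harmonisation
    with palindrome and proxy rules; instrument diagnostics (F-statistics,
    variance explained, I2_GX, Steiger directionality, power); the
    univariable estimator suite (inverse-variance weighted with
    multiplicative random effects, weighted median, MR-Egger, MR-PRESSO);
    multivariable MR with the Sanderson-Windmeijer conditional
    F-statistic and covariance-aware modified Cochran's Q; and a
    synthetic GWAS summary-statistics generator with recorded ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
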