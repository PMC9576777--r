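Package: pqtlmr
Title: Proteome-Wide Two-Sample Mendelian Randomization with pQTL Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization of plasma protein levels on
    disease outcomes using protein quantitative trait loci (pQTLs) as
    instruments. Provides summary-statistic harmonization, LD clumping with
    cis/trans instrument classification, an estimator battery (Wald ratio,
    fixed- and multiplicative-random-effect inverse-variance weighting,
    correlated-instrument IVW, MR-Egger, contamination mixture) with
    heterogeneity, pleiotropy and MR-PRESSO outlier diagnostics, Bayesian
    multi-trait colocalization with subset search, two-step mediation
    analysis by the product and delta methods, a phenome-wide MR screen with
    layered Bonferroni correction, and a seeded synthetic summary-statistic
    generator for validation of the full decision pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
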