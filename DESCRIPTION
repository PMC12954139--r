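Package: omam
Title: Allometric Indexing of Adult Body Weight and Overweight Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the optimized multivariate allometric model (OMAM) of adult
    body weight, W = c * A^x * H^y with a sex-specific constant, on the log
    scale by ordinary least squares with optional stepwise selection.
    Computes the corrected weight score WC (measured over predicted weight),
    derives empirical-percentile reference thresholds for overweight
    classification, runs the three-condition equation-validation protocol on
    an independent subgroup, and compares WC-based against BMI-based
    overweight criteria for cardiometabolic screening with paired McNemar
    tests. Includes seeded synthetic-cohort generators so every pipeline
    stage is testable without access to the original cohorts, and a
    command-line interface over the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
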