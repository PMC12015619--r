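Package: oebench
Title: Risk-Adjusted Benchmarking of Broad-Spectrum Antibiotic Use with
    Smoothed Observed-to-Expected Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hospital-level benchmarking of broad-spectrum antibiotic use in
    older-adult pneumonia inpatients. Provides a synthetic generator for
    hospital-clustered admission cohorts, the study inclusion/exclusion
    cascade, a random-intercept (hospital) logistic risk-adjustment model,
    TRIPOD-style validation metrics (C-statistic, calibration slope,
    accuracy), and smoothed observed-to-expected ratios per hospital with
    cluster bootstrap confidence intervals and league-table categorization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
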