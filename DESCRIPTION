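Package: regconf
Title: Confidence Estimation and Empirical Prediction Intervals for Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-prediction confidence estimation for regression models used in
    cheminformatics and immunoinformatics (QSAR, MHC-peptide binding). Implements
    neighborhood error-transfer (CONFINE) and local response-variance (CONFIVE)
    confidence estimators together with six reference estimators (number of
    neighbors, difference to neighbor mean, average distance, local
    cross-validation, local sensitivity, bootstrap-ensemble variance), rank
    normalization of raw scores, calibration into empirical-quantile confidence
    intervals, the confidence-error correlation (CEC) and confidence-associated
    prediction improvement (CAPI) evaluation metrics, and a nested
    cross-validation benchmarking harness with a seeded Friedman-function data
    generator and a 9-mer peptide encoder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
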