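Package: hrvcc
Title: Heart Rate Variability and Cardiac Complexity Analysis for
    Ambulatory Interbeat-Interval Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long ambulatory interbeat-interval (RR/NN)
    recordings: artifact filtering (band thresholds plus a moving central-
    window percentage rule), time-domain and frequency-domain heart rate
    variability (AVNN, HR, RMSSD, LF and HF spectral power), detrended
    fluctuation analysis scaling exponents, allometric-aggregation fractal
    dimension, and multiscale sample entropy. Includes heart-rate adjustment
    of cardiac measures, Bonferroni-grouped two-group comparisons with
    Cohen's d, two-step hierarchical moderated regressions of symptom
    scores on sex and cardiac measures, and a synthetic-data generator
    producing realistic interval series and two-group cohorts so every
    stage of the pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
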