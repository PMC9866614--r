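Package: edafreq
Title: Frequency-Spectrum Features for Stress Detection from Wrist
    Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and evaluation pipeline for detecting
    stress from low-rate (4 Hz) wrist-measured skin conductance.
    Segments labelled electrodermal activity (EDA) recordings with a
    sliding window into single-state segments, computes one-sided
    amplitude spectra and multi-band spectral features (band mean,
    standard deviation and maximum plus the half-energy frequency),
    augments them with windowed sequence statistics, and evaluates
    classifiers under leave-one-subject-out cross-validation with
    accuracy, F1 and time-to-detection accounting. Includes an adapter
    for the WESAD dataset's per-subject records and a synthetic
    multi-subject EDA cohort generator (Poisson skin-conductance-response
    trains with a bi-exponential pulse shape) so the whole pipeline is
    testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
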