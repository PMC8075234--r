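Package: gaitfall
Title: Fall-Risk Classification from Pelvis Smartphone IMU Data in the
    Six-Minute Walk Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and classification pipeline for six-minute walk
    tests recorded with a smartphone inertial sensor worn at the posterior
    pelvis. Detects foot strikes from anterior-posterior acceleration,
    segments steps into turns and straightaways from pelvis yaw rate,
    extracts a 62-feature per-step catalog (temporal, descriptive and
    frequency-domain measures including the first-quartile FFT fraction,
    the even/odd harmonic ratio and spectral peak distinction), aggregates
    them into 248-feature participant vectors for four step sets, ranks
    features by correlation-based feature selection, Relief-F or
    extra-trees importance, and evaluates fall-risk classifiers with
    leave-one-out random forests scored by accuracy, sensitivity,
    specificity, Matthews correlation and F1 with summed-rank model
    selection. Includes a synthetic gait generator that produces labeled
    cohorts with ground-truth events so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
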