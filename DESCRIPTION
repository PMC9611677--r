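Package: tremorkit
Title: Contactless Hand-Tremor Quantification from Hand-Landmark Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the dominant movement frequency and amplitude of a
    tremoring hand from markerless 21-point hand-landmark trajectories
    (as produced by video hand trackers) and from accelerometer traces.
    Signals are band-pass filtered (0.5-15 Hz), cut into non-overlapping
    2-s segments, transformed with the FFT, and per-segment spectral peaks
    are fused into one robust per-recording estimate using automatic
    three-standard-deviation outlier elimination. Includes evaluation
    statistics for validating video against accelerometer measurements
    (absolute error, RMSE, Pearson correlation) and for quantifying
    before/after-medication changes in Parkinson's disease cohorts, plus
    a seeded synthetic-recording generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
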