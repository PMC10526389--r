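Package: mstatebci
Title: EEG Microstate Analysis and Motor-Imagery BCI Performance Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis and prediction of
    motor-imagery brain-computer interface (MI-BCI) performance. Provides
    global field power (GFP) and global map dissimilarity (GMD), GFP-peak
    extraction, modified k-means clustering of peak topographies into
    microstate template maps, backfitting of continuous EEG to microstate
    label sequences, the four classical microstate parameters (mean
    duration, occurrence, time coverage, transition probabilities),
    cluster-number selection criteria (global explained variance,
    cross-validation criterion, dispersion), common spatial pattern (CSP)
    feature extraction with cross-validated motor-imagery classification,
    correlation screening of microstate parameters against MI accuracy, a
    two-feature linear discriminant predictor of high/low BCI performers
    with per-session leave-one-out cross-validation and ROC analysis, a
    spectral-entropy baseline predictor, and seeded synthetic-data
    generators with planted microstate structure and planted
    microstate-to-performance links for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
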