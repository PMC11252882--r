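Package: tilevote
Title: Ensemble Majority Voting for Tile-Level Invasive Cancer Detection in Whole Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tile-level ensemble-classification framework for invasive
    carcinoma (IC) detection in whole-slide histopathology images. Provides
    polygon-annotation to tile-label mapping by the tile-center rule,
    stratified train/test splitting and division of training slides into
    equal groups preserving clinical covariate proportions, per-model
    Dice-optimal binarization threshold calibration on out-of-division
    tiles, majority-vote aggregation with the binomial ensemble-success
    theory, a spatial agreement statistic, and agreement visualisations.
    A seeded base-model simulator with controllable accuracy, calibration
    shift and inter-model correlation stands in for GPU-trained
    convolutional networks so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    grid,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
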