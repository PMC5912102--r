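Package: gazetraits
Title: Predicting Personality-Trait Score Ranges from Everyday Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for predicting low/medium/high personality
    trait score ranges from head-mounted eye-tracking recordings of everyday
    behaviour. Provides gaze preprocessing with erroneous-sample marking and
    participant screening, dispersion-threshold fixation detection, saccade
    and blink detection, a 207-dimensional feature bank over 50%-overlapping
    sliding windows (raw gaze statistics, 8x8 gaze heatmaps, oculomotor event
    statistics, and gaze n-gram histogram features), data-driven tertile
    binning of trait scores, per-trait random-forest classification under
    nested cross-validation with window-size and feature-subset selection,
    chance/most-frequent/label-permutation baselines with bootstrap
    confidence intervals, context-split prediction reliability, and a
    synthetic gaze-cohort generator with configurable trait-to-oculomotor
    effect sizes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
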