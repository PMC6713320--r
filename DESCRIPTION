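Package: sonolift
Title: Music-Based Biofeedback Analysis for the Barbell Deadlift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for a movement-sonification biofeedback system
    for the barbell deadlift. Reads and validates optical motion-capture
    marker trajectories, derives per-frame spine-bend and barbell-foot
    distance and their calibrated non-dimensional forms, maps them through a
    logistic function to audio-control parameters (sample-rate degradation
    quality and front/surround channel gains) and renders them onto WAV
    audio, segments captures into deadlift repetitions from the vertical bar
    path, summarizes sessions, and reproduces the normality-branched
    statistical evaluation pipeline (paired and independent comparisons,
    group homogeneity, nested expertise models, rating tests). A synthetic
    motion generator with exact ground truth makes every stage testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
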