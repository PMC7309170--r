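Package: stdta
Title: Transition-Aware Human Activity Recognition by Standard-Deviation
    Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recognises postural and locomotion transitions in wearable-sensor
    streams. Fuses 50 Hz tri-axial accelerometer data with 5 Hz barometer data,
    extracts per-window statistical features, classifies eight basic activities
    with a probabilistic margin classifier, and flags transition activities with
    a state machine driven by the trend of the windowed standard deviation of
    the acceleration magnitude (STD-TA). Includes a seeded synthetic stream
    generator, a least-squares procedure for the transition-gate weights, and
    confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    rpart,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
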