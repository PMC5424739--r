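Package: gazefuzz
Title: Fuzzy-System Target Selection for NIR Camera-Based Gaze Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects when a user is gazing at a screen target in order to
    select it, from near-infrared eye images. Segments the pupil and corneal
    glint with a circular-Hough rough estimate refined by an adaptive-mask
    Chan-Vese active contour, extracts three intention features (pupil
    accommodation by template matching on the pupil-size series, cumulative
    gaze change over a short dwell window through a glint-compensated
    four-point bilinear calibration, and Gabor-bank texture of the monitor
    image around the gaze point), and fuses them in a Mamdani-style fuzzy
    system with entropy-optimised linear membership functions and a choice of
    defuzzifiers (FOM, MOM, LOM, COG, BOA). Includes a ground-truthed
    synthetic session generator and equal-error-rate / ROC evaluation tools.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
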