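Package: posefall
Title: Speed-Aware Fall Detection from Pose Keypoint Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short clips of human pose keypoint time series
    (the 33-landmark MediaPipe Pose schema) into seven posture classes,
    with an emphasis on separating sudden falls from ordinary activities
    of daily living. Implements the full pipeline: reading and validating
    keypoint tables, frame-count standardization by ordered random
    subsampling, Kalman smoothing of tracked landmark trajectories,
    central-body-point construction, instantaneous keypoint speed
    features, min-max normalization, a transformer encoder sequence
    classifier with LSTM and GRU baselines (trained with Adam, SGD or
    AdamW under cosine learning-rate decay and early stopping), and
    evaluation via per-class precision/recall/F1, confusion matrices and
    fall-vs-rest ROC/AUC. A synthetic skeleton-motion generator emulates
    labeled clips with class-specific kinematic signatures so the whole
    pipeline runs without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
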