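Package: fogvision
Title: Video-Based Freezing-of-Gait Recognition from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-vision pipeline for recognizing freezing of gait (FOG) in
    Parkinson's disease from 2D human-pose keypoint time series (OpenPose BODY_25
    layout). Provides scale normalization via the expanded enclosing rectangle,
    derivation of kinematic signals (speeds, accelerations, knee angles, left-right
    keypoint distances), sliding-window time- and frequency-domain features including
    band powers and the freezing index, staged gradient-boosted-tree classifiers
    (walk/turn motion stage, then stage-specific FOG models) with gain-ranked forward
    feature selection, SMOTE balancing and transition-window removal, episode
    extraction with minimum-duration postprocessing, leave-one-subject-out evaluation
    with window- and episode-level metrics, and a synthetic gait simulator so the
    whole pipeline is testable without clinical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    xgboost,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
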