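Package: actimage
Title: Activity-Image Encoding and Convolutional Classification of
    Upper-Limb Motion-Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing upper-limb lifting movements recorded with
    optical motion capture, aimed at separating post-stroke from healthy
    movement patterns. Marker trajectories are clipped to the movement,
    mirrored onto a common (right) side, resampled, and encoded as
    fixed-size multi-channel "activity images" of displacement, velocity,
    acceleration and jerk features. A small convolutional neural network
    (implemented in base R), three flat baseline classifiers (random
    forest, linear support-vector machine, logistic regression), a
    Gaussian-process Bayesian hyperparameter search and a marker-ablation
    experiment driver operate on these images. A synthetic cohort
    generator built on minimum-jerk trajectories emulates healthy and
    post-stroke lifting kinematics so that the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
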