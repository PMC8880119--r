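Package: tensiowork
Title: Muscle-Tendon Work Estimation from Wearable Shear-Wave Tensiometry and IMU Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for wearable estimation of triceps surae
    muscle-tendon work during outdoor walking on slopes. Converts two-channel
    tendon-tap accelerometer recordings into Achilles tendon shear wave speed
    via normalized cross-correlation with cosine subsample peak interpolation,
    calibrates wave speed to ankle moment against balance-plate sway trials,
    segments strides from accelerometry with IMU-derived spatiotemporal
    metrics and terrain-slope assignment from a course map, corrects
    inter-system start delays by level-stride cross-correlation, computes
    soleus and gastrocnemius forces, velocities, excursions, powers, work
    loops and stride work from moment-arm models, and fits incline/decline
    slope-sensitivity regressions of zero-referenced net work. Includes a
    synthetic gait-and-sensor generator with retained ground truth so every
    stage is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
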