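Package: overstride
Title: Overstriding and Braking-Force Prediction from Wearable IMU Segment Angles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating overstriding and peak braking force during
    treadmill and overground running from wearable inertial measurement units
    (IMUs). Implements drift-managed sagittal segment-angle estimation from
    orientation quaternions (standing-pose calibration and a per-frame
    gravity/joint-axis reference-frame redefinition), cross-correlation time
    synchronization against motion capture, ground-reaction-force gait-event
    detection and stride metrics, and random-intercept linear mixed-model
    analysis with ICC and marginal/conditional R-squared. Ships a synthetic
    running-data generator with known ground truth (planar forward-kinematics
    skeleton, IMU mounting offsets, heading drift, sensor start delays) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
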