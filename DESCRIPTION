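Package: elbowcal
Title: Sensor-to-Segment Calibration and 3-DOF Elbow Joint Angles from
    Inertial Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating anatomically meaningful elbow joint
    angles (flexion/extension, carrying angle, pronation/supination) from
    body-worn inertial measurement units (IMUs). Implements three
    sensor-to-segment calibration strategies - static N-pose, functional
    calibration from gyroscope hinge-axis estimation, and manual
    alignment - together with quaternion kinematics, the ZXY Euler
    decomposition of the International Society of Biomechanics elbow
    convention, per-repetition agreement metrics (range-of-motion error,
    root-mean-square error after demeaning, offset), and repeated-measures
    summaries with generalized eta squared effect sizes. A virtual-subject
    simulator generates ground-truth upper-limb kinematics and corrupted
    IMU streams (mounting misalignment, sensor noise, heading drift,
    imperfect static posture) so the whole pipeline can be validated
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
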