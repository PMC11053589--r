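Package: gaitfusion
Title: IMU Sensor Fusion and Knee-Angle Gait Analysis with Synthetic
    Verification
Version: 0.1.0
Authors@R:
    person("gaitfusion", "developers", email = "dev@gaitfusion.invalid",
           role = c("aut", "cre"))
Description: Tools for estimating body-segment inclination and knee joint
    angles from wearable six-axis inertial measurement units (IMUs).
    Implements stationary gyroscope bias self-calibration, an extended
    Kalman filter observer that tracks the gravity direction in the sensor
    frame, two-sensor joint-angle computation, and time-series agreement
    statistics (time-offset alignment, resampling, RMSE). A physics-based
    synthetic motion module generates damped-pendulum and treadmill-gait
    trajectories with realistic sensor noise, bias and full-scale
    saturation, so the whole pipeline can be verified against known ground
    truth without hardware. Includes an in-process metrics store with
    per-column filter semantics mirroring a cloud measurement API.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
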