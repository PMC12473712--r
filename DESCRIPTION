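Package: vrimu
Title: Synthetic Inertial Signals and Convolutional Identification from
    VR Controller Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms 6-DoF hand-controller pose recordings (3D position
    plus unit-quaternion orientation) into body-frame accelerometer and
    gyroscope signals by quaternion kinematics, with optional zero-phase
    low-pass conditioning.  Includes a seeded generator of subject-distinct
    virtual-reality throw gestures, feature assembly across pose/Euler/IMU
    modalities, three small one-dimensional convolutional network
    architectures (plain, attention-pooled, and multi-input) trained with
    Adam and cross-entropy, and a cross-day one-vs-rest evaluation protocol
    reporting macro F1, AUC, FAR and FRR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
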