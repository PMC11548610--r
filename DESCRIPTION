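Package: canegait
Title: Cane-Mounted IMU Gait Analysis and Frailty Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for inertial measurement unit (IMU) recordings
    taken from an instrumented walking cane. Provides zero-phase Butterworth
    low-pass filtering, jerk-norm detection of cane ground contacts,
    gait-cycle segmentation, per-cycle time-domain features (RMS of
    acceleration, peak angular velocity, stride time) and band-limited
    spectral features (mean power frequency from a 512-point FFT with a
    periodic Hamming window), rank-based two-group comparison with effect
    sizes, and tenfold cross-validated classification of physical frailty
    with five classifier families. A synthetic cane-gait generator with
    group-dependent presets and questionnaire-based frailty labelling
    supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    MASS,
    class,
    rpart,
    e1071,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
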