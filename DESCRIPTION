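Package: vrgaze
Title: Head-Compensated Eye-Movement Analytics for Virtual-Reality Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gaze recordings made with head-mounted
    virtual-reality eye trackers: head compensation of eye-in-head gaze via
    quaternion head pose, adaptive velocity-threshold (Engbert-Kliegl) saccade
    and fixation detection with physiological event filters, per-scenario
    scanpath features (fixation duration, saccade duration and amplitude,
    normalized scanpath saliency, ambient/focal time-course bins, head-motion
    metrics), rank-based and mixed-model group statistics with false discovery
    rate correction, and nested cross-validated PCA+SVM group classification.
    Includes a calibrated synthetic VR-session generator that produces
    ground-truth-annotated gaze streams with main-sequence saccade kinematics,
    tracker noise and bursty data loss for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
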