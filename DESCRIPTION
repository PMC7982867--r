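Package: spinenav
Title: Simulation and Accuracy Evaluation of Ultrasound-Based Spine Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the accuracy, robustness and anatomical
    coverage of intraoperative-ultrasound (iUS) based spine navigation in a
    fully simulated setting. Provides a parametric lumbosacral spine phantom
    with multi-resolution CT-like volumes and anatomical labelmaps, a tracked
    freehand ultrasound sweep simulator with bone-echo and shadow image
    formation, fiducial-based ground-truth alignment, a bone-surface
    point-cloud to CT-surface rigid registration (trimmed iterative closest
    point), target registration error (TRE) metrics with success /
    level-mismatch classification, error propagation across vertebral levels
    with distance regression, a first-hit ray-cast coverage model over
    anatomical labels, and linear and binomial mixed-effect analyses linking
    coverage to accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    RANN,
    jsonlite,
    RNifti
Config/testthat/edition: 3
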