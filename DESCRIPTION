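Package: etdrift
Title: Drift Correction and Long-Term Evaluation for Electronic Tongue
    Sensor Arrays
Version: 0.1.0
Authors@R:
    person("etdrift", "developers", email = "etdrift@example.org",
           role = c("aut", "cre"))
Description: Tools for correcting sensor drift in multi-session
    potentiometric electronic-tongue (sensor array) experiments. Implements
    four drift-correction methods as fit/apply pairs: additive correction
    relative to the whole sample set, additive correction relative to
    reference samples, multi-sensor linear (affine) correction between
    sessions, and component correction by orthogonal removal of the drift
    direction, including a modified variant that subtracts the drift
    component twice from later sessions only. Includes the matching
    evaluation protocol (canonical linear discriminant analysis trained on
    the baseline session, threefold stratified cross-validation, per-class
    accuracies and confusion matrices, relative Euclidean centroid
    distances in discriminant space), pretreatment rules for raw
    acquisitions, a synthetic generator of drifting sensor-array
    experiments with temperature response, memory carryover and
    cross-contamination, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
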