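Package: primsense
Title: Classification of Upper-Extremity Functional Primitives from
    Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying upper-extremity functional primitives
    (reach, transport, reposition, idle) from multi-channel inertial
    measurement unit (IMU) recordings. Implements the full pipeline used
    in sensor-based quantification of rehabilitation dose: z-score
    normalization, sliding-window statistical featurization (mean,
    standard deviation, minimum, maximum, root mean square), four
    classifiers under one contract (linear discriminant analysis,
    Gaussian naive Bayes, RBF-kernel support vector machine, k-nearest
    neighbors), stratified repeated-holdout and leave-one-subject-out
    evaluation with positive predictive value, confusion-matrix and
    ROC/AUC metrics, a train/test timing harness, and an exhaustive
    search over sensor-site subsets and sensor types. A synthetic-data
    generator emulates a structured tabletop reaching task with
    minimum-jerk kinematics, forearm grasp rotations, correlated trunk
    sway, and per-subject variability, supporting controlled method
    studies when patient recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
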