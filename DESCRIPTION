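Package: imupose
Title: Full-Body Posture Recognition and Corrective Guidance from
    Wearable IMU Quaternions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognition and quantitative evaluation of static full-body
    postures (e.g. yoga asanas) measured by eleven body-worn inertial
    measurement units streaming orientation quaternions.  Implements
    sensor-to-animation-frame calibration, a two-stage classifier (a
    backpropagation neural network over waist rotation-matrix features
    routing to per-category fuzzy C-means models over body-relative
    features), cumulative-likelihood smoothing of per-frame results into
    per-instance recognition, a per-posture Bayesian network of
    child-given-parent conditional Gaussians that scores the standard
    degree of every body segment, and translation of flagged segments
    into corrective guidance (orientation word plus angular extent in
    radians).  Includes a seeded synthetic-data generator emulating the
    statistical structure of multi-subject posture databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
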