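Package: neckbrace
Title: Kinematics, Calibration and Movement Analysis for a 6-DOF Serial-Chain Neck Brace
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolkit for a six-revolute-joint serial-chain wearable
    neck brace that measures head-neck range of motion. Implements
    Denavit-Hartenberg forward/inverse kinematics, design-phase workspace
    analysis (trunk-frame point clouds, sphere fitting, exhaustive parameter
    search with clearance checking), potentiometer-to-angle polynomial
    calibration validated against motion capture, zero-phase angle filtering,
    a six-step surface-EMG linear-envelope pipeline, trigger-based stream
    synchronization, movement-cycle segmentation with time normalization,
    pre/post-operative outcome statistics, and a ground-truthed synthetic
    session generator (digital twin) used for validation and cohort-level
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
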