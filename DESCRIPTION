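Package: mocapfit
Title: Automatic Skeleton Scaling, Marker Registration, Inverse Kinematics
    and Residual Reduction for Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("Mocapfit", "Developers", email = "mocapfit@example.org",
           role = c("aut", "cre"))
Description: Sequential optimization pipeline that turns labeled optical
    marker trajectories and force-plate recordings into a subject-specific
    rigid-body skeleton and dynamically consistent joint kinematics and
    kinetics. Stages include functional joint-center and axis estimation,
    anthropometric-prior based body-segment scaling, marker registration,
    inverse kinematics via a bilevel maximum a posteriori fit, linear
    center-of-mass and root-rotation fitting against ground reaction
    forces, and a final residual-force minimizing adjustment of segment
    masses and kinematics. Includes readers and writers for TRC marker
    files and MOT-style force and coordinate files, and a synthetic gait
    generator that produces dynamically consistent ground-truth trials
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
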