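Package: respifem
Title: Finite-Element Simulation of Respiratory Muscle Mechanics and Thorax Deformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear finite-element machinery for simulating thorax deformation
    driven by respiratory muscle contraction. Implements an active Hill-type
    transversely isotropic hyperelastic continuum model of skeletal muscle
    (intercostals and diaphragm) with mixed displacement-pressure treatment of
    incompressibility, follower pressure loads, frictionless contact via Lagrange
    multipliers, and an incremental-static Newton solver. Ships synthetic
    rib-cage and diaphragm-dome geometry generators, spatial activation fields
    and temporal activation waveforms for the inspiratory and expiratory muscle
    groups, and the standard respiratory kinematic read-outs (bucket-handle and
    pump-handle rib angles, chest diameters, diaphragm dome descent).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
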