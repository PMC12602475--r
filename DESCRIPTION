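Package: kneesim
Title: Multibody Tibiofemoral Joint Simulation of Passive Knee Flexion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-static multibody simulation of the tibiofemoral joint.
    Anatomical body frames and the clinical joint coordinate system
    (flexion-extension, abduction-adduction, internal-external rotation,
    joint and clinical translations) are built from named landmarks;
    fifteen ligament and capsule bundles follow a nonlinear (toe-region)
    force-elongation law with per-element slack lengths initialised at
    full extension; cartilage-on-cartilage load transfer uses a penalty
    contact model evaluated on triangle meshes.  Prescribed passive
    flexion drives a five-coordinate static equilibrium solve at each
    step, producing the dependent joint motions and ligament tension
    profiles.  Includes a parametric synthetic-knee generator, mesh and
    trajectory file I/O, and a regression-based kinematic validation
    pipeline that compares simulated against experimental trajectories
    parameterised by flexion angle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
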