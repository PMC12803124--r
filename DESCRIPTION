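Package: shapemech
Title: Statistical Shape Atlas Surrogates for Biventricular Wall Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building synthetic statistical shape atlases of the
    biventricular heart, estimating unloaded reference geometries from an
    empirical end-diastolic pressure-volume relationship, running quasi-static
    incompressible Holzapfel-Ogden finite-element simulations of diastolic
    filling and active systolic contraction, projecting simulated deformations
    back into atlas principal-component space, and training a multilayer
    perceptron surrogate that predicts deformed shape modes from unloaded
    shape modes, chamber pressures and material parameters. Includes
    point-cloud comparison metrics (Hausdorff distance, average nearest
    neighbour distance, overlap percentage) for validating predicted
    geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
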