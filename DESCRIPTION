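Package: mechanoheal
Title: Chemo-Mechano-Biological Simulation of Damage-Induced Healing in Soft Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of damage-induced growth and remodeling in
    soft biological tissues. Collagen damage by interstrand delamination is
    modeled as finite-strain anisotropic plasticity via a multiplicative
    split of the deformation gradient; damage stimulates a matrix
    metalloproteinase / growth factor reaction system that degrades damaged
    and deposits new collagen; the resulting change of reference mass
    density drives volumetric growth enforced by a penalty constraint.
    Includes a material-point (Gauss point) driver with backward-Euler
    internal-variable integration and a mixed three-field (H1-P0) nonlinear
    finite-element solver on hexahedral meshes, together with ready-made
    species, sensitivity, biaxial-tension and indentation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
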