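Package: mixanalyze
Title: Structural and Transport Analysis of Molecular Dynamics Trajectories of Binary Eutectic Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of
    hydrogen-bonded liquid mixtures such as menthol-fatty acid eutectics.
    Computes site-site radial distribution functions, coordination numbers,
    angular and combined (radial/angular, radial/radial) distribution
    functions, spatial distribution functions and particle-density (Dens)
    profiles; detects hydrogen bonds with geometric distance/angle criteria
    and reports count distributions, Gaussian-fit average bond numbers and
    percent occupancies; decomposes non-bonded interaction energy into
    Coulomb and Lennard-Jones 12-6 terms; and estimates transport
    properties: center-of-mass mean-square displacements, the beta
    log-log-slope profile, Einstein self-diffusion coefficients, bond-vector
    reorientation dynamics, and Green-Kubo shear viscosity from the
    off-diagonal pressure tensor. Ships synthetic-trajectory generators
    (ideal gas, Brownian, ballistic, rotational diffusion, hydrogen-bonded
    dimers, Lennard-Jones fluid, Ornstein-Uhlenbeck pressure series) with
    closed-form ground truth so every estimator is testable without
    large-scale simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    minpack.lm,
    pracma,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
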