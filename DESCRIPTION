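Package: thrombosim
Title: Multiscale Simulation of Donor-Specific Thrombus Growth Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale multiscale simulator of platelet deposition and thrombus
    growth in voxelized vessel geometries. Couples a lattice Boltzmann solver for
    quasi-static blood flow, a finite-volume convection-diffusion-reaction solver
    for the soluble agonists ADP and thromboxane A2, a rejection-free lattice
    kinetic Monte Carlo model of platelet motion, adhesion and detachment with
    shear-dependent von Willebrand factor enhancement, and donor-specific
    feed-forward neural-network surrogates of platelet calcium signaling trained
    on synthetic pairwise-agonist-scanning calcium traces. Includes a synthetic
    donor cohort generator, threshold calibration, and a scenario suite for
    agonist inhibition, endothelial antagonists and tissue-factor-driven thrombin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
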