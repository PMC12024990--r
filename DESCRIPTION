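Package: nanolga
Title: Coupled Lattice Boltzmann-Lattice Gas Simulation of Nanoparticle
    Transport in Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mesoscopic simulation of ligand-coated nanoparticle diffusion
    in the tumor extracellular matrix and in cell-packed tumor tissue.
    Stochastic voxel geometries (collagen fiber networks, tumor/stromal
    cell packings, regular sphere arrays) host a BGK lattice Boltzmann
    solver (D3Q19 flow, D3Q7 temperature, Boussinesq buoyancy) coupled to
    a lattice-gas particle tracker with an exact exponential drag
    integrator and stochastic node-migration rule.  Nanoparticle-wall
    physical chemistry (van der Waals, electrostatic double layer, Lewis
    acid-base) governs adhesion and detachment, and external thermal and
    magnetic-gradient fields act on the particles.  Analysis tools fit
    per-axis diffusion coefficients from mean-squared-displacement curves
    and implement the equivalent-viscosity reduction used to coarse-grain
    the fiber matrix for tissue-scale runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
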