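Package: ionperm
Title: Ion Permeation Analysis with a Brownian-Dynamics Toy Channel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying selective cation permeation through a sodium
    channel selectivity filter. Provides a coarse-grained toy-channel
    Hamiltonian with two rings of tethered carboxylate beads and a
    two-rotamer lysine plug, overdamped Langevin and Metropolis samplers,
    and the full analysis chain used for mechanistic permeation studies:
    occupancy-conditioned multi-ion potentials of mean force by Boltzmann
    inversion with block-bootstrap errors and minimax barrier extraction,
    radial distribution functions and data-driven binding cutoffs,
    per-frame ion/carboxylate complex classification, permeation-event
    detection with two-plane hysteresis, staged free-energy perturbation
    with exponential and Bennett acceptance-ratio estimators plus exact
    quadrature oracles, and RMSD/RMSF, ion-density and screened-Coulomb
    potential maps. Reads standard PDB/DCD trajectories via 'bio3d' and a
    native labeled-XYZ interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
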