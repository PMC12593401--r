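Package: cspkit
Title: Crystal Structure Prediction with Surrogate Potentials and
    Quasi-Harmonic Free-Energy Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for molecular crystal structure prediction
    (CSP): symmetry-constrained random structure generation with van der Waals
    close-contact screening and rigid-body compression, molecular shell and
    n-mer extraction with tethered Langevin sampling, ensemble-uncertainty
    active learning for interatomic-potential training data, pluggable energy
    models (pair potentials, point-charge Ewald electrostatics, damped two-body
    dispersion with an Axilrod-Teller-Muto three-body correction, and a
    trainable descriptor-regression surrogate), BFGS crystal relaxation with
    variable-cell and fixed-volume modes, harmonic phonons and quasi-harmonic
    Gibbs free energies via Birch-Murnaghan equation-of-state fitting, and
    polymorph ranking reports (energy-density landscapes, MAE/RMSE/Kendall
    statistics, cluster RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
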