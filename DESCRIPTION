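Package: alchemr
Title: Desk-Scale Alchemical and Multi-Scale Free-Energy Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for staged alchemical annihilation free-energy
    calculations on toy fixed-charge and Drude-polarizable molecular
    systems: Metropolis Monte Carlo sampling with lambda-Hamiltonian
    replica exchange, soft-core Lennard-Jones potentials, the Zwanzig
    (exponential) estimator, Bennett's acceptance ratio (BAR) and the
    Non-Boltzmann-Bennett (NBB) reweighting estimator, bookend
    corrections between a sampling Hamiltonian and a target Hamiltonian,
    tailored force-field generation that matches equilibrium bond and
    angle values to a target-minimized geometry, hydration free-energy
    thermodynamic cycles, and RMSD/MSD/R-squared agreement metrics.
    Validated against closed-form statistical mechanics at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
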