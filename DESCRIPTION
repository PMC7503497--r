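Package: evbfep
Title: Empirical Valence Bond Free Energy Profiles via FEP/Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale empirical valence bond (EVB) machinery for reactive
    free-energy calculations: two diabatic force-field states coupled by a
    constant off-diagonal term, lambda-mapping Langevin sampling, the free
    energy perturbation / umbrella sampling (FEP/US) estimator on the
    energy-gap coordinate, calibration of the coupling and gas-phase shift
    against reference activation and reaction free energies, and
    transition-state-theory conversions between barriers and rate constants.
    Ships a synthetic reacting-system generator (Morse-bonded donor/hydride/
    acceptor triad plus a displaced harmonic bath with tunable reorganization
    energy) and an analytically solvable harmonic surrogate used as a Marcus
    oracle for the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
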