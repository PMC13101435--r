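Package: perosense
Title: Degradation-as-Signal Digital Twin for Enzyme-Coupled Optical
    Glucose Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models optical glucose sensing films whose transduction
    mechanism is controlled chemical degradation: glucose oxidase (GOx)
    converts glucose to hydrogen peroxide, which accelerates oxidative
    breakdown of the sensing layer and produces a glucose-dependent loss
    of optical signal. Provides a closed-form 0D pseudo-first-order
    kinetic model parameterised from design-target half-lives, a
    transient Michaelis-Menten peroxide pathway with exposure matching
    against the constant-rate surrogate, an explicit finite-difference
    1D reaction-diffusion thin-film solver, signal-detection
    discrimination metrics (d-prime, Gaussian classification error)
    with Monte Carlo validation, kinetic design-space grid search and
    sensitivity sweeps, and a three-stage calibration protocol with a
    synthetic noisy-trajectory generator. Includes a command-line
    interface for all workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
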