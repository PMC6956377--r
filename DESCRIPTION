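Package: microrelease
Title: Diffusion-Limited Release Kinetics of Drug-Loaded Microspheres
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward modelling and parameter estimation for in-vitro drug
    release from polymeric microspheres. Implements the non-steady-state
    Fickian sphere model with external boundary-layer mass-transfer
    resistance: the eigenvalue series solution with roots of the
    transcendental equation beta*cot(beta) + L - 1 = 0, the Biot number L,
    and its diffusion-controlled large-L simplification. The effective
    diffusion coefficient and the boundary-layer mass-transfer coefficient
    are estimated per release curve by residual-sum-of-squares minimisation
    with a genetic algorithm followed by simplex refinement, with replicate
    aggregation and an identifiability diagnostic for the mass-transfer
    coefficient. Also provides gravimetric mass-loss and water-uptake
    formulas, burst-fraction and phase-rate release descriptors, a
    synthetic-data generator for validation studies, a Crank-Nicolson
    finite-difference cross-check of the series solution, and strict CSV
    input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
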