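Package: docklock
Title: Multiscale Dock-Lock Kinetics of Fibril Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale modelling of amyloid-fibril elongation by the
    two-step dock-lock mechanism. Provides a coarse-grained chiral-dumbbell
    model with overdamped Brownian dynamics (compiled Euler-Maruyama
    integrator), second-order docking rate constants via the
    Northrup-Allison-McCammon finite-domain committor construction,
    two-dimensional free energy surfaces from umbrella sampling with
    weighted-histogram analysis, locking rate constants from Langer's
    multidimensional barrier-crossing theory, a dock-lock microkinetic rate
    law, analytic population-balance solutions for fibril length
    distributions (including Lambert-W monomer depletion and warped time),
    seeded fibril-growth simulations, and maximum-likelihood extraction of
    locking rate and Michaelis constants from length-versus-time traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
SystemRequirements: C++17
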