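Package: homeostab
Title: Stability Analysis of Homeostatic Intrinsic Plasticity in Neurons
    and Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses the stability of homeostatic regulation of intrinsic
    neuronal excitability.  Implements a three-stage firing-rate model (rate
    filter, activity sensor, perfect-integrator threshold controller) together
    with closed-form and numerical stability criteria: Routh-Hurwitz tests for
    real and complex network eigenmodes, critical and oscillation-free
    integrator time constants, characteristic polynomials of multi-stage
    feedback cascades, parallel controllers, and sector-based (Aizerman)
    global criteria for nonlinear f-I curves.  Includes fast fixed-step
    simulation of the (possibly nonlinear, noisy, heterogeneous) rate model,
    a conductance-based leaky integrate-and-fire network with an
    activity-dependent homeostatic bias current, weight-matrix fixture
    generators with controlled spectra, and a command-line interface for
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
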