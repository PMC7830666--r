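Package: multichaos
Title: Multi-Chaotic Analysis of Time Series via Generalized Largest
    Lyapunov Exponent Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates spectra of generalized largest Lyapunov exponents
    (GLLE) for scalar time series by tracking nearest-neighbor divergence
    in delay-embedded phase space under Minkowski p-norms, including
    fractional orders 0 < p < 1.  The width of the GLLE(p) spectrum
    quantifies the degree of multi-chaos of a signal.  Includes
    seed-controlled simulators for benchmark chaotic systems (logistic and
    Henon maps, Lorenz and Rossler flows), delay and embedding-dimension
    estimation (autocorrelation, mutual information, correlation integral,
    Cao's method), Grassberger-Procaccia correlation dimension, and
    logistic-regression scoring of inter-beat (R-R) interval series for
    discrimination between normal and pathological cardiac rhythm classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
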