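Package: pdmaxent
Title: Accelerated Primal-Dual Solvers for Non-Smooth Regularized Maximum
    Entropy Density Estimation
Version: 0.1.0
Authors@R:
    person("pdmaxent", "developers", email = "pdmaxent@example.org",
           role = c("aut", "cre"))
Description: Fits regularized maximum entropy (MaxEnt) density estimates over
    discrete site grids using accelerated nonlinear primal-dual hybrid
    gradient (NPDHG) algorithms whose proximal ascent step is a
    Kullback-Leibler divergence, giving closed-form Gibbs updates and
    stepsizes governed by the cheap max-column-norm of the feature operator
    rather than its largest singular value. Supports elastic-net,
    non-overlapping group-lasso, and sup-norm penalties, warm-started
    regularization-path fitting with model-specific optimality-gap stopping
    rules, an accelerated forward-backward splitting baseline on the dual,
    and presence-only data-preparation operators (ecoregion-weighted
    empirical distributions, prior imputation, min-max feature scaling)
    together with a reproducible synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
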