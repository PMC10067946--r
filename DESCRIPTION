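Package: fenolong
Title: Longitudinal Modelling of Multiple-Flow Exhaled Nitric Oxide
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating longitudinally assessed multiple-flow
    exhaled nitric oxide (FeNO) to covariates through the steady-state
    two-compartment model of NO in the lower respiratory tract. Provides
    a unified three-level hierarchical Bayesian nonlinear mixed-effects
    model fitted by Metropolis-within-Gibbs MCMC with a non-negativity
    constraint on alveolar NO, two-stage estimators built on per-session
    nonlinear least squares, the Hogman-Merilainen three-flow algorithm,
    and nonlinear mixed-effects fits, a synthetic-data generator for
    three-level multiple-flow FeNO studies, and a simulation harness
    computing bias, interval coverage, power and type-I error across
    estimation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    nlme,
    lme4
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
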