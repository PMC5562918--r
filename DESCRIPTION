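Package: npfilter
Title: Weight-Free Particle Filtering and Online Learning for Nonlinear
    State-Space Models
Version: 0.1.0
Authors@R:
    person("npfilter", "developers", email = "npfilter@example.org",
           role = c("aut", "cre"))
Description: Continuous-time nonlinear Bayesian filtering with an unweighted
    (neural) particle filter: particles are propagated by the prior drift and
    corrected by a gain-weighted innovation, with the gain estimated
    empirically from the ensemble cross-covariance or learned online by
    gradient ascent on the observation log-likelihood.  Includes an
    Euler-Maruyama simulator for state-space diffusions, a model zoo
    (double-well hidden dynamics with linear and sigmoidal sensory channels,
    high-dimensional Ornstein-Uhlenbeck and bimodal families), reference
    filters (Kalman-Bucy, weighted bootstrap particle filter with systematic
    resampling, ensemble Kalman-Bucy), online maximum-likelihood and Hebbian
    parameter learning with forward sensitivity propagation, and benchmark
    drivers for particles-versus-dimension scaling studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
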