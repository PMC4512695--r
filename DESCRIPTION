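Package: clonalgrowth
Title: Colored-Noise Stochastic Models of Clonal Population Growth
Version: 0.1.0
Authors@R:
    person("Eleanor", "Woods", email = "ewoods@example.org",
           role = c("aut", "cre"))
Description: Simulators and closed-form solutions for multiplicative-noise
    models of clonal population growth driven by Gaussian colored noise
    (an Ornstein-Uhlenbeck growth rate with magnitude D and correlation
    time tau_c).  Provides exact-in-distribution noise generation,
    autocorrelation and two-state Markov intermittency diagnostics, a
    linear exponential-of-integral model and a stochastic logistic
    self-regulation model with time-dependent log-normal and
    truncated-reciprocal-Gaussian population densities, moment and local
    growth-rate statistics, a fitness/survivability layer for selection
    sweep experiments, and a Kolmogorov-Smirnov validation harness
    comparing ensembles against the analytic densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
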