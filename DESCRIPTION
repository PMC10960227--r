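Package: bisectmeta
Title: Temporal Bisection, Metacognition, and Hierarchical Bayesian Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-interval temporal-bisection sessions
    with a second-order (metacognitive) forced choice. Provides a forward
    generative observer model, ideal-observer re-sorting of trial pairs, the
    Metacognitive Index (a ratio of ideal to subjective best/worst variance
    ratios), trial-series descriptives (binned means, histograms,
    autocorrelation, coefficient of variation), and a hierarchical Bayesian
    measurement model of bisection precision and metacognitive precision with
    cross-condition coupling, fitted by MCMC (JAGS), with R-hat convergence
    diagnostics, highest-density intervals, DIC model comparison, and
    posterior-predictive Metacognitive Index distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
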