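Package: mbimpulse
Title: Stability-Landscape Impulse-Response Models of Microbiome Recovery
    After Antibiotics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the recovery of microbial community diversity after a
    short antibiotic course as the impulse response of an overdamped harmonic
    oscillator on a stability landscape.  Provides closed-form two- and
    three-parameter displacement models (with and without a transition to an
    alternative stable state), Faith's phylogenetic diversity with bootstrap
    rarefaction, Bayesian model fitting by adaptive MCMC with convergence
    diagnostics, Bayes-factor model selection via bridge sampling, a
    study-shaped synthetic data generator with known ground truth, and a
    generalized Lotka-Volterra scan for two-state (bistable) dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
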