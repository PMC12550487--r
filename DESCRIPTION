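Package: predrate
Title: Predation Rates from Binary Molecular Gut-Content Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of per-pair predation rates
    from binary molecular prey-detection data. Combines laboratory feeding
    trials, which calibrate logistic prey-DNA decay (digestion) curves, with
    field-caught predator tests, where detection arises from a latent Poisson
    predation process thinned by digestion. Provides the closed-form
    detectability integral, joint MCMC inference over both data sources via
    JAGS, convergence diagnostics, posterior-predictive goodness-of-fit
    checks, an event-based simulator with known ground truth, and an
    abundance-weighted community-scale biocontrol indicator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
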