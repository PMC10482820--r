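Package: itcmodels
Title: Inter-Temporal Choice Models: Simulation, Estimation, and Parameter Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with eleven prominent models of inter-temporal
    (delay-discounting) choice, spanning discounted-utility models (exponential,
    hyperbolic, double exponential, generalized hyperbolic, hyperboloid,
    generalized hyperbola, constant sensitivity, additive utility) and
    attribute-wise models (proportional difference, the inter-temporal choice
    heuristic, and the trade-off model). Provides choice-probability and
    log-likelihood functions, seeded response simulation, generators for three
    standard choice-set designs (the 27-item Kirby monetary choice
    questionnaire, a 380-item amount-by-delay factorial grid, and
    participant-tailored effect sets), synthetic participant populations,
    Bayesian estimation (individual and hierarchical) with WAIC model
    comparison and convergence diagnostics, and pipelines for parameter
    recovery and cross-choice-set parameter consistency analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
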