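Package: vascat
Title: Hierarchical Bayesian Modeling of Visual Analogue Scale Speech
    Categorization in Accelerated Longitudinal Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the development of speech categorization with
    continuous visual analogue scale (VAS) identification tasks. Simulates
    accelerated-longitudinal VAS studies with known ground truth, fits a
    hierarchical Bayesian four-parameter logistic psychometric model with
    trial-level heteroscedastic (log-quadratic in continuum step) response
    variance via a purpose-built adaptive MCMC sampler, extracts per-subject
    categorization slope and response-variability indices, and analyzes their
    development with linear mixed-effects growth-curve models, marginal
    predictions, and practice-effect contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    coda,
    lme4,
    lmerTest,
    minpack.lm,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
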