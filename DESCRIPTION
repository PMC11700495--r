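Package: fishmpm
Title: Age-Structured Matrix Population Models for Fishes from Minimal
    Life-History Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constructs age-structured (Leslie) matrix population models for
    fish species from a minimal set of life-history parameters: von
    Bertalanffy growth, length-mass allometry, age and length at maturity,
    maximum age, and a stock-recruitment productivity parameter. Natural
    mortality follows the Lorenzen mass-dependent model, so no direct
    survival estimates are needed. Provides a density-dependent variant with
    compensatory (Beverton-Holt type) recruitment, computes seven standard
    demographic metrics (damping ratio, resilience, generation time, stable
    age distribution, reproductive value, sensitivity and elasticity
    matrices), and propagates life-history parameter uncertainty by
    multivariate-normal Monte-Carlo simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
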