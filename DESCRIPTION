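Package: multistress
Title: Multi-Stressor Survival Analysis with Multiplicative Null Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-stressor field transplant experiments
    on sessile marine invertebrates. Simulates individual-level survival,
    colony-size and fecundity data under a blocked plate/panel design with
    density-dependent survival; fits binomial, Poisson and Gaussian
    generalised linear models with Wald and likelihood-ratio tests; converts
    logistic coefficients into treatment survival probabilities relative to a
    control; builds multiplicative (and additive) null expectations for the
    combined-stressor arm with parametric-bootstrap standard errors; and
    classifies the stressor interaction as antagonistic, synergistic, or
    indistinguishable. Includes a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
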