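Package: embycatch
Title: Fleet-Wide Harbour Porpoise Bycatch Estimation from Electronic
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of total harbour porpoise (Phocoena phocoena) bycatch
    in set-gillnet fleets from electronic-monitoring (EM) records of fishing
    days. Provides harmonization of effort records to the vessel-day-rectangle
    resolution, a stratified bycatch-per-unit-effort (BPUE) ratio estimator
    with non-parametric bootstrap intervals, a negative-binomial mixed model
    with vessel/year random intercepts and exponential-covariance spatial
    random fields fitted by Laplace approximation, bias-corrected aggregation
    of natural-scale predictions with parametric-bootstrap intervals,
    standardized effort and standardized BPUE indices, pinger-regulation
    scenario contrasts, and PBR/mPBR sustainable-removal limits. A synthetic
    data generator reproduces the assumed generative model with known
    parameters so the whole pipeline is testable without confidential fleet
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    geosphere,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    glmmTMB,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
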