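Package: vodscore
Title: Continuous Disease-Progression Scores from Graphical Models of
    Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a continuous veno-occlusive disease (VOD) progression
    score for each patient in a retrospective haematopoietic stem-cell
    transplant cohort from multivariate physiological time series, by
    inferring a soft-random-geometric-graph graphical model per patient,
    measuring discretised Hellinger distances between the sampled graph
    posteriors, and running Metropolis-Hastings inference on the relative
    scores.  Scores from several cohorts are aligned through inter-reference
    distances and clinician severity orderings.  A vector-variate Gaussian
    Process with a matrix-normal likelihood then links the learnt scores to
    mixed-type pre-transplant attributes, so that the score of a prospective
    patient can be learnt pre-transplant by MCMC, including extrapolation
    under elicited priors.  Pre-transplant risk factors are ranked by a
    leave-one-variable-out likelihood drop.  A synthetic-cohort generator
    with a latent severity that deforms the inter-parameter correlation
    structure makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
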