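Package: mesoproj
Title: Group Comparison of Brain-Wide Axonal Projection Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical pipeline for detecting group differences in
    animal-by-region axonal projection-fraction matrices from anterograde
    tracing experiments. Implements reliability thresholding of weak
    regions, injection-volume power-law normalization, a per-region
    general linear model with injection-centroid covariates, a one-tailed
    bootstrap test on the mean condition coefficient, multiscale region
    clustering by continuous-time Markov stability, leave-one-out
    logit-boost classification of animals with exact binomial
    significance, and a synthetic cohort generator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
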