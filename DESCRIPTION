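Package: rtadapt
Title: Local Adaptation Analysis for Reciprocal Transplant Experiments
Version: 0.1.0
Authors@R:
    person("RTE", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing reciprocal transplant experiments (RTE) on
    tree seedling cohorts: validation and tabulation of individual-level
    germination/survival/growth records, a synthetic RTE generator with the
    statistical structure the analysis assumes, from-scratch fitting of
    binomial-logit, censored-geometric and Gaussian age-interaction models,
    least-squares (adjusted) means under unbalanced designs with a combined
    home-vs-away / local-vs-foreign contrast, and permutation-based
    conditional inference trees with random-forest variable importance.
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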