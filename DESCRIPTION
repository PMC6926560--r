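Package: resilscreen
Title: Composite Mental-Health Screening from SOC-13 and GHQ-12 with
    Likelihood-Ratio Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the 13-item Sense of Coherence scale (SOC-13), the 12-item
    General Health Questionnaire (GHQ-12) and the 9-item Beck Depression
    Inventory short form, combines dichotomized SOC and GHQ into a four-level
    composite indicator of mental resilience/vulnerability, and evaluates the
    indicator against a binary reference standard using multi-level likelihood
    ratios, Bayes post-test probabilities, predictive values and nonparametric
    ordinal ROC/AUC. Includes Wilson score intervals and proportion tests for
    prevalence summaries, Little's MCAR test to support available-case analysis,
    and a seeded synthetic-cohort generator (category-level and latent-trait
    item-level) for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
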