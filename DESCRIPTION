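Package: phenoselect
Title: Additive Dose-Response Phenology Models with Climate-Scenario Aware
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates additive dose-response phenology models for winter
    wheat from daily station weather and phase-boundary observations, combines
    per-covariate dose-response curves into binomial-logit composite models
    over all covariate subsets, and selects among them with three strategies:
    best fit to ground-truth phenology (Max_GT), least sensitivity to climate
    scenario input data over a reference period (Max_CS), and the compromise
    of the two (Opt). Includes root-sum-of-squares propagation of per-covariate
    scenario error over covariate subsets, projection of selected model chains
    onto scenario ensembles with period medians and 30-year rolling trends,
    and a synthetic-data generator for end-to-end validation with a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nloptr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
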