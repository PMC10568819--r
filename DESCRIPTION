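Package: dyadDD
Title: Delay Discounting Measurement and Dyadic Analysis for Parent-Child Cohorts
Version: 0.1.0
Authors@R: person("dyadDD", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring and analysing monetary delay discounting in
    parent-child dyads. Implements an adjusting-amount (staircase) task engine
    with simulated choice agents, indifference-point scoring and choice-log
    validation, systematic-responding quality control, the ordinal
    area-under-the-curve discounting measure, anthropometric scoring (BMI,
    percent over median BMI, LMS z-scores against a user-supplied reference),
    economic-scarcity covariate coding, correlation screens and stacked
    parent-child mixed models with predictor-by-member interaction tests under
    Benjamini-Hochberg false-discovery-rate control, a synthetic family-cohort
    generator with known latent truth for validation, and an end-to-end
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
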