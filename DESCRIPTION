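Package: mgtkit
Title: Simulation and Mixed-Model Analysis of the Maastricht Gambling Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies built on the Maastricht Gambling Task (MGT), a
    six-box binary lottery task for measuring risk-taking behavior. Provides
    the complete 125-configuration trial space and randomized session plans,
    scoring of the task's dependent variables (payoff-SD risk score, choice
    optimality, response time) with trial-type averaging and interquartile-range
    outlier filtering, a synthetic-cohort generator for factorial
    probiotics-by-stimulation designs with known ground truth, linear
    mixed-model fits with nested random intercepts, estimated-marginal-means
    contrast tables with Bonferroni correction, and a parameter-recovery
    harness for validating the full simulate-score-fit pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
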