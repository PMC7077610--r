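Package: spinpulse
Title: Affect Spin, Pulse, and Discontinuous Growth Modelling of Skill
    Acquisition and Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying intraindividual affect variability and its
    relation to skill acquisition and adaptive performance in repeated-measures
    designs with an abrupt task change. Scores circumplex affect reports
    (valence and activation composites from PANAS-style items), computes
    per-person variability statistics (affect spin as the circular standard
    deviation of affect directions, affect pulse as the standard deviation of
    affect intensities), builds discontinuous growth-model time codes for a
    sessions-with-change-point design, fits the corresponding ladder of
    random-intercept mixed-effects growth models by maximum likelihood, and
    generates complete synthetic studies with known ground truth so every
    pipeline stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
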