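Package: telebp
Title: Evaluating Blood Pressure Telemonitoring with Routinely Collected Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of home blood-pressure
    telemonitoring against surgery (clinic) measurements in routinely
    collected primary-care data. Implements four complementary analysis
    methods: standardisation with stratification (including the relative
    risk reduction ratio with a non-parametric bootstrap), standardisation
    with exact-criteria 1:1 matching and paired t-tests, regression
    adjustment for a propensity score, and random-coefficient longitudinal
    modelling with DerSimonian-Laird meta-analytic pooling across practices.
    Also quantifies terminal-digit (end-digit) preference, and ships a
    synthetic-cohort generator reproducing the main bias mechanisms of such
    roll-outs (confounded enrolment, white-coat effect, unequal reading
    frequencies, end-digit rounding, BP-dependent withdrawal, measurement
    error) so every method can be validated against a known ground truth.
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
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
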