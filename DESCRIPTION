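Package: apcbound
Title: Bounded Age-Period-Cohort Analysis of Survey-Weighted Time-Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for age-period-cohort (APC) analysis under partial
    identification. Separates estimable nonlinear deviations from the
    non-identified linear effects using weighted orthogonal polynomial
    contrasts, estimates the canonical solution line (theta1 = alpha_L +
    pi_L, theta2 = gamma_L + pi_L) by weighted least squares on person-day
    microdata, bounds the linear effects by a grid search under a
    substantive constraint on the location of the net total age minimum,
    and assembles net total age, period, and cohort effect curves with
    identification bands. Includes a synthetic generator for
    survey-weighted Lexis-structured time-diary data with known ground
    truth, and an end-to-end gender-stratified pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
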