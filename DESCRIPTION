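Package: stratamr
Title: Stratified Non-Linear Mendelian Randomisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-linear Mendelian randomisation for individual-level cohort
    data with a survival outcome. Partitions the sample into strata of the
    exposure by the residual or the doubly-ranked method, estimates a
    localised average causal effect (LACE) in each stratum as the ratio of
    the instrument-outcome association from Cox regression on the age
    timescale to the instrument-exposure association from linear regression,
    and reconstructs the causal dose-response curve by meta-regression of
    the LACE estimates on derivatives of fractional polynomials, with
    linearity and trend tests. Includes sample-perturbation sensitivity
    analysis combined by Rubin's rules, instrument-validity diagnostics in
    strata, a synthetic cohort generator with configurable instrument-effect
    heterogeneity and participation selection, and weighted genetic score
    construction from external variant weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
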