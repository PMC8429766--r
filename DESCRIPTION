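Package: vibropitch
Title: Simulation and Model Fitting for Vibrotactile Pitch Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying vibrotactile pitch perception, built around the
    power-law metamer model in which perceived pitch of a sinusoidal vibration
    equals amplitude^k times frequency. Provides generative mouse and human
    observer models, the adaptive procedures used in rodent go/no-go and human
    two-alternative forced-choice experiments (a bias-adaptive double-sigmoid
    trial scheduler, a custom frequency-discrimination staircase, a 3-down/1-up
    detection staircase and a bout-based detection procedure with exact binomial
    thresholding), maximum-likelihood cumulative-Gaussian psychometric fitting
    with bootstrap confidence intervals, pitch-exponent estimation with
    confidence-interval significance gating, descriptive sum-of-exponentials
    equal-intensity fits, V-shaped sensitivity-curve aggregation, and end-to-end
    parameter-recovery studies on synthetic sessions.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
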