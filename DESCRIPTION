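Package: aoalearn
Title: Accumulator Models of Word Age-of-Acquisition Distributions
Version: 0.1.0
Authors@R:
    person("AoA", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling population age-of-acquisition (AoA)
    distributions of early-learned words as the outcome of a stochastic
    accumulator process: a child acquires a word after the N-th exposure to a
    relevant event, with exposures arriving under a power-law time-varying
    sampling rate. The resulting AoA laws are the gamma (constant rate,
    N-accumulator), Weibull (changing rate, 1-accumulator) and
    Weibull-gamma / generalized-gamma (both) families, plus a logistic
    alternative. Provides closed-form CDF/pdf/hazard/mean/quantile layers,
    hazard-shape classification, an event-level simulator and a synthetic
    MCDI-style norms generator, per-word maximum-likelihood fitting with BIC
    model selection, and downstream analyses (median AoA, class and age
    cross-tabulations with chi-square tests, attribute correlations with
    Fisher confidence intervals, and moving-average developmental trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
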