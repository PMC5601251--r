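Package: reprosen
Title: Decomposing Reproductive Ageing in Long-Lived Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing age-related variation in breeding success from
    longitudinal colony-monitoring data on long-lived seabirds. Fits binomial
    mixed models with crossed individual and year random intercepts, selects
    among null, linear, quadratic and piecewise (threshold) age functions by
    AIC with profile-deviance confidence intervals on breakpoints and
    AIC-weight model averaging of predicted age curves, and decomposes
    population-level trajectories into within-individual improvement and
    senescence, selective appearance and disappearance, and first-attempt and
    terminal effects using within-group centring. Includes an individual-based
    simulator of breeding histories (annual and biennial breeding tactics,
    deferral, quality-dependent mortality) so every inference stage can be
    validated against known truth, plus a dense Gauss-Hermite quadrature
    oracle for the marginal likelihood of small crossed-effects models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
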