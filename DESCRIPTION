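Package: herdgrowth
Title: Hierarchical Bayesian Ricker Models for Multi-Herd Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits linearized Ricker growth models to annual abundance indices
    from several ungulate herds at once, with herd-level random effects on the
    intrinsic growth rate and optional temporal random effects on the growth
    rate and on the strength of density dependence. Provides per-herd model
    selection by posterior mean deviance, carrying-capacity estimation from
    the growth response's x-intercept, a three-component decomposition of
    abundance variance into demographic, density-independent and
    density-dependent stochasticity, cross-herd inverse regressions against
    carrying capacity, a synthetic multi-herd data generator, and an
    end-to-end pipeline with CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
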