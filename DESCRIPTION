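Package: mapsdem
Title: Demographic Trend Analysis for Constant-Effort Banding Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian estimation of breeding-season demographic rates for
    migratory songbirds monitored by constant-effort mist-netting networks
    such as MAPS (Monitoring Avian Productivity and Survivorship). Implements
    a hierarchical transient Cormack-Jolly-Seber mark-recapture model with a
    residency mixture, a Poisson log-linear model for adult counts with
    station random effects and lognormal overdispersion, a binomial model for
    relative breeding productivity (juvenile proportion), and recruitment
    derived from the joint posterior of abundance and survival. Includes an
    adaptive Metropolis-within-Gibbs sampler, Gelman-Rubin and highest
    posterior density diagnostics, regional trend summaries on a
    percent-per-year scale, and a fully seeded synthetic-data generator that
    emulates multi-region banding networks with transients, sex-structured
    recapture, human-footprint and effort covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
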