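Package: zoodemog
Title: Bayesian Siler Demography for Zoological Census Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates age-specific mortality from census records of animals
    in zoological institutions using the five-parameter Siler hazard model
    fitted by Metropolis-Hastings MCMC under left truncation, right
    censoring and interval-valued birth dates. Provides posterior densities
    of life expectancy, lifespan equality and first-year mortality,
    calibrated Kullback-Leibler comparison of posteriors across periods and
    sexes, product-limit life tables, least-squares reconstruction of wild
    population Siler mortality from stage-structured survival data, a
    synthetic census generator with known ground truth, and an end-to-end
    analysis pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
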