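Package: hemivar
Title: Partitioning X-Linked and Autosomal Additive Genetic Variance in
    Lifespan and Aging from Hemiclone Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating and partitioning additive genetic variance
    in lifespan and demographic aging between the X chromosome and the
    autosomes, within and between the sexes, from chromosome substitution
    ("hemiclone") line experiments. Provides a synthetic-data generator for
    the hemiclone sampling design, maximum-likelihood fitting of Gompertz
    mortality models to interval-censored per-vial death schedules, Bayesian
    multi-response Gaussian mixed models with parameter-expanded priors
    fitted by a blocked Gibbs sampler, restricted maximum likelihood fits
    with biologically motivated variance constraints and likelihood ratio
    tests, Gelman-Rubin convergence diagnostics, and posterior-aware derived
    statistics (additive genetic variance, evolvability coefficients, the
    intersexual genetic correlation, and X-linkage proportions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
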