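Package: wfrcens
Title: Weibull-Frechet Lifetime Inference Under Progressive Type-II Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Likelihood and Bayesian inference for the four-parameter
    Weibull-Frechet lifetime distribution from progressively type-II
    censored survival data.  Provides the distribution functions in
    overflow-safe log-space form, construction of removal schemes
    (one-point and binomial-removal), progressive censored-sample
    simulation, profile maximum likelihood with observed-information and
    delta-method confidence intervals, percentile and studentized
    parametric bootstraps, Metropolis-Hastings-within-Gibbs posterior
    sampling with balanced squared-error and balanced-LINEX point
    estimation, Kolmogorov-Smirnov goodness of fit with the exact
    one-sample null distribution, and a seeded Monte-Carlo study harness.
    Ships two small survival-time datasets used throughout the examples,
    including gastric-cancer survival times of patients under combined
    chemotherapy and radiotherapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
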