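Package: snpcount
Title: Poisson Count Regression with Semi-Nonparametric Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of Poisson regression models for
    overdispersed count data in which the unobserved heterogeneity on the log
    mean follows a flexible semi-nonparametric density (a squared polynomial
    of length K times the standard normal density), evaluated by Gauss-Hermite
    quadrature. Includes the closed-form Negative Binomial (Poisson-gamma)
    benchmark, forward selection of the polynomial length by likelihood-ratio
    testing, goodness-of-fit reporting (deviance, AIC, BIC), Gaussian kernel
    density estimation for visual comparison of heterogeneity distributions,
    seeded simulation designs with log-gamma, normal, bimodal and trimodal
    heterogeneity, and a command-line interface for fitting models to tabular
    crash-frequency data with exposure offsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pracma,
    foreign,
    optparse
Config/testthat/edition: 3
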