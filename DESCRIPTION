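Package: bifcop
Title: Bi-Factor and Second-Order Copula Models for Ordinal Item Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copula extensions of the Gaussian bi-factor and second-order
    (hierarchical) factor models for ordinal item response data grouped into
    non-overlapping domains.  Bivariate normal, Student-t, Gumbel and reflected
    Gumbel copulas link items to a common factor and to group-specific factors;
    joint probabilities are evaluated by nested Gauss-Legendre quadrature so
    that only one-dimensional integrals are required regardless of the number
    of groups.  Provides two-step inference-functions-for-margins (IFM) and
    full maximum-likelihood estimation, seeded simulation from both models,
    tail-asymmetry diagnostics based on polychoric semi-correlations, a
    heuristic AIC-based copula selection algorithm, Vuong model comparison,
    and the limited-information M2 goodness-of-fit statistic with RMSEA2 and
    maximum bivariate discrepancy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mvtnorm,
    statmod,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    yaml,
    withr
Config/testthat/edition: 3
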