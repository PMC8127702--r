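Package: halfsibG
Title: Half-Sib Breeding Designs, Bayesian G-Matrix Estimation and
    Multivariate G-Matrix Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of nested paternal half-sib breeding
    designs for multivariate quantitative genetics. Provides a generator for
    half-sib field experiments with known genetic architecture, Gibbs samplers
    for univariate variance components and multivariate additive genetic
    covariance (G) matrices under conjugate inverse-Wishart priors,
    permutation-based null distributions with highest-posterior-density
    machinery, and a suite of G-matrix comparison statistics: Krzanowski
    common-subspace analysis, the fourth-order genetic covariance tensor,
    multivariate breeder's-equation response predictions, the R metric for
    the effect of genetic covariances on the rate of adaptation, and random
    skewers. Selection gradients are estimated from sire means by
    least-squares or conjugate Bayesian regression, including a composite
    fitness component built from male and female fitness proxies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
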