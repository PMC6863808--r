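Package: mixirtsim
Title: Monte Carlo Simulation Toolkit for Mixture Polytomous IRT Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sample-size requirements of mixture polytomous
    item response models for rating-scale data. Implements the restricted mixed
    generalized partial credit model (rmGPCM) and the mixed partial credit model
    (mPCM) in their adjacent-category logit form, marginal maximum likelihood
    estimation by an EM algorithm with Gauss-Hermite quadrature and a
    Newton-type refinement stage, observed-information standard errors,
    replication-level accuracy indices (root median squared error, standard
    error bias, confidence interval width, coverage, Spearman concordance),
    information-criterion class enumeration (AIC, BIC, CAIC, AIC3, SABIC), and
    an orchestrator that runs full simulation conditions from a bundled set of
    empirically derived generating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nnet,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
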