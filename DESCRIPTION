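Package: oslm
Title: Operation-Specific Learning Models for Within-Test Practice Effects
Version: 0.1.0
Authors@R:
    person("Alex", "Moreno", email = "alex.moreno@example.org",
           role = c("aut", "cre"))
Description: Bayesian estimation of the linear logistic test model (LLTM) and
    its operation-specific learning extensions (OSLM, RWLLTM, RWOSLM and
    constrained mixed variants) for binary responses to rule-based figural
    matrix tests. Item difficulty is decomposed over a hypothesized
    item-by-component structure matrix, and within-test practice effects are
    modelled per component, optionally as person-varying multivariate-normal
    random effects with an LKJ correlation prior. Includes a built-in
    No-U-Turn sampler with analytic gradients, rank-normalized split R-hat,
    WAIC and Pareto-smoothed importance-sampling LOO, posterior predictive
    checks based on a pairwise odds-ratio statistic, a synthetic-data
    generator emulating a Carpenter-rule progressive-matrices design, and
    reporting utilities (external-measure correlations, Rasch
    variance-explained regression, tidy difficulty trajectories).
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
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
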