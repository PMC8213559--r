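Package: magscale
Title: Hierarchical Bayesian Analysis of Magnitude-Estimation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing psychophysical magnitude-estimation data:
    simulation of trial-level rating experiments under Stevens' power law
    with standard, reversed and unidirectional response formats; response
    recoding and trial exclusion; repeated-measures and mixed ANOVA on log
    ratings with Greenhouse-Geisser correction and generalized eta squared;
    hierarchical Bayesian power-law and linear mixed models fitted by MCMC;
    marginal likelihoods by iterative bridge sampling with log Bayes factors;
    WAIC and Pareto-smoothed importance-sampling LOO; and posterior
    predictive checks, orchestrated by an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    jsonlite,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
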