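Package: kcforest
Title: k-Dependence Causal Forest Bayesian Network Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian network classifiers for tabular (clinical and
    epidemiological) data: naive Bayes, tree-augmented naive Bayes (TAN),
    the k-dependence Bayesian classifier (KDB), averaged one-dependence
    estimators (AODE), and the k-dependence causal forest (KCF) -- an
    ensemble of k-dependence trees obtained by rooting the
    conditional-mutual-information maximum spanning tree at every attribute
    and averaging the submodel posteriors. Includes equal-frequency
    discretization, CSV/ARFF readers, Markov-blanket extraction with
    dependency-mass statistics, 10-fold cross-validation, balanced accuracy,
    the Friedman rank test, sign-test win/draw/loss records, and a seeded
    discrete Bayesian-network sampler for fully reproducible synthetic
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
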