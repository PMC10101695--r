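Package: gselect
Title: Genomic Selection with Bayesian Hyperparameter Optimization and Phenotype Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genomic-prediction toolkit for continuous and discrete traits:
    reads genotype matrices (CSV, PLINK text), validates and encodes them
    (additive dosage, one-hot), filters markers by minor-allele frequency,
    and creates seed-reproducible persisted data splits (train-validation-test,
    cross-validation with held-out test set, nested cross-validation).
    Prediction models include a native RR-BLUP with REML variance-component
    estimation, native Gibbs samplers for Bayes A, Bayes B and Bayes C, and
    penalized linear and logistic baselines. A built-in tree-structured Parzen
    estimator performs sequential hyperparameter search with median-rule trial
    pruning, and a linear-mixed-model simulator generates phenotypes with a
    known causal architecture and target heritability for controlled model
    assessment. Results of multiple runs are summarized into tidy tables and
    heat maps, and fitted models can be re-applied to new genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyselect,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
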