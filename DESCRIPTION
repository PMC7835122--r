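Package: conceptbench
Title: Few-Shot Learning of Novel Visual Categories from Hierarchy Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A seeded, desk-scale benchmark for studying how features taken
    from different depths of a trained visual hierarchy support learning
    novel visual categories from very few labelled examples.  The package
    generates synthetic part-based category worlds, trains a small
    convolutional hierarchy on a set of base categories, extracts feature
    matrices from four named taps (a category-tuned conceptual layer and
    three progressively earlier generic layers), runs a factorial one-vs-all
    few-shot classification protocol with elastic-net logistic classifiers,
    scores each classifier with the signal-detection sensitivity index
    d-prime, and summarises the results with bootstrap confidence intervals
    and paired sign-flip permutation contrasts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
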