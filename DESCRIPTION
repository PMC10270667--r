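Package: bantor
Title: Distance Regression for Multitask and Multisession Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Regression framework relating distances between repeated
    (multitask, multisession) weighted brain networks to covariate
    differences. Computes five network similarity/dissimilarity metrics
    (Kolmogorov-Smirnov on edge-weight distributions, Jaccard on
    thresholded key-edge sets, Euclidean, Pearson correlation distance,
    and the log-Euclidean Riemannian metric on symmetric
    positive-definite matrices), assembles the pairwise distance design
    with absolute-difference regressors, and fits a crossed
    random-effects mixed model (3M_BANTOR) with Satterthwaite inference
    alongside standard F-test and permutation MDMR baselines. Includes a
    simulator of symmetric positive-definite connectivity matrices with
    copula-coupled, covariate-dependent signal regions and a factorial
    study harness for type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    lme4,
    lmerTest,
    optparse,
    readr,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
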