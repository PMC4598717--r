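Package: plastimap
Title: Tutoring-Induced Neural Normalization Analysis for Pre/Post fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying intervention-induced
    normalization of brain activity in two-group, two-session task fMRI
    designs. Provides a seeded synthetic BOLD cohort generator, motion
    despiking and quality-control gating, event-related general linear
    model contrast estimation with a canonical haemodynamic response
    function, voxelwise group inference with Monte-Carlo cluster-extent
    family-wise-error correction, Bayesian two-group estimation on region
    betas, multivariate pattern classification with leave-one-out
    cross-validation and permutation testing, and a Brain Plasticity
    Index relating pre-to-post pattern change to behavioural gains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    nortest,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
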