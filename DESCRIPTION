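Package: progpath
Title: Progression Path Modeling from Static Omics Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs disease-progression trajectories from static molecular
    profiles. Provides large-margin feature selection for nonlinear regression on
    censored survival outcomes (endpoint decomposition, expected hypothesis margins,
    l1-constrained hinge minimization solved by fixed-point recursion), self-tuning
    spectral clustering on a mutual k-nearest-neighbor graph with rotation-based
    cluster-number estimation and resampling consensus, EM fitting of discretized
    (possibly branching) principal curves under isotropic fixed-variance Gaussian
    noise with elbow-based bandwidth selection, and construction of cluster-level
    progression trees with covariate mapping (Spearman), polynomial gene
    trajectories, Kaplan-Meier summaries and PCA views. Includes seeded generators
    for branching-manifold benchmark data with survival outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
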