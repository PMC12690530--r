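Package: ivdnet
Title: Cytokine Networks, Disc Morphometry and Viscoelastics for Diabetic
    Intervertebral Disc Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing intervertebral
    disc (IVD) pathology in mouse models of type 2 diabetes. Implements
    differential cytokine screening (median pseudo-replicate collapse,
    out-of-range missingness filtering, Welch's t-test, fold-change analysis),
    cytokine correlation-network construction and comparison (Pearson
    correlation thresholding, eigenvector and betweenness centrality, Louvain
    community detection, k-hop reachability, Jaccard network similarity),
    contrast-enhanced micro-CT disc morphometry (Gaussian smoothing,
    contour-interpolated whole-disc masks, nucleus pulposus segmentation,
    NPVF/NIDI/DHI metrics), cyclic-compression viscoelastic analysis (loading
    slope, loss tangent, hysteresis energy), and glucose-tolerance-test AUC
    phenotyping. Ships seeded synthetic-data generators with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
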