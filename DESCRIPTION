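Package: caspectral
Title: Correspondence Analysis as Ordination, Spectral Clustering and Graph Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A spectral toolkit for nonnegative contingency tables and binary
    incidence matrices viewed as bipartite networks. Correspondence analysis (CA)
    is computed from the degree-standardized table and exposed under its three
    equivalent readings: paired row/column scores that maximize the correlation of
    scores across edges (ordination / gradient analysis), relaxed normalized-cut
    cluster labels of the one-mode similarity network obtained by stochastic
    complementation (spectral clustering), and principal-coordinate embeddings of
    that network (graph drawing and dimensionality reduction). Includes the
    eigengap heuristic for choosing the cluster count, k-means partitioning of the
    spectral embedding, a recursive cluster-then-ordinate procedure for data that
    mix clusters and gradients, an arch-effect diagnostic, stylized bipartite
    network generators with planted structure, revealed-comparative-advantage
    binarization for weighted tables, and a reproducible file-based pipeline with
    a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
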