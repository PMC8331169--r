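Package: somgcn
Title: Self-Organizing Map Clustering and Coexpression Hub Discovery for
    Multi-Tissue RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering hub regulators in
    multi-tissue transcriptomes, motivated by haustorium development in
    parasitic plants. Normalizes raw RNA-seq counts with the trimmed mean
    of M-values (TMM), filters genes by coefficient of variation, clusters
    expression profiles on a hexagonal self-organizing map, builds
    correlation-thresholded gene coexpression networks with a normal
    quantile cutoff, partitions them by fast-greedy modularity
    optimization, ranks hub transcription factors by degree and
    betweenness centrality, extracts first- and second-layer neighborhoods
    of a focal regulator, and tests term over-representation with a
    hypergeometric model under Benjamini-Hochberg control. Ships seeded
    synthetic-data generators (negative-binomial tissue counts with
    planted clusters, latent-factor coexpression modules with designated
    hubs, planted-partition benchmark graphs) so every stage has a
    ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
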