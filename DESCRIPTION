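Package: netprio
Title: Network Topology Based Core-Target Prioritization for Toxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for network-toxicology core-target
    prioritization. Computes fourteen protein-protein interaction (PPI)
    network centrality indices (MNC, EPC, Bottleneck, Stress, Radiality,
    betweenness, closeness and friends) from scratch, intersects per-metric
    hub lists, runs a seeded machine-learning workflow (z-score
    standardization, K-means with elbow selection, Isolation Forest anomaly
    detection, PCA projection), aggregates direction-aware per-index ranks
    into a composite importance score, applies a core-gene decision rule,
    and provides exact hypergeometric overlap tests and GMT-based
    over-representation analysis. Ships seeded synthetic-data generators
    (scale-free networks with planted super-hubs, target lists with
    controlled overlap, clustered feature clouds, enriched gene-set
    collections) so every stage is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
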