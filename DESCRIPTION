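Package: mirsnpnet
Title: Pathway-Based miRSNP Switching Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of miRNA-associated polymorphisms (miRSNPs)
    at the pathway level. Implements exact cumulative hypergeometric
    over-representation tests with Benjamini-Hochberg false discovery rate
    control, gene-set (GMT) enrichment of curated risk-gene lists, pairwise
    pathway crosstalk networks, consensus integration of multi-tool
    miRNA-target predictions, multi-database miRSNP evidence filtering,
    construction and topological analysis (degree, betweenness centrality,
    power-law fit) of bipartite miRNA-pathway networks annotated with
    miRSNPs, and enumeration of miRSNP-miRNA-risk gene-pathway regulatory
    axes. Ships a seeded synthetic-data generator with planted structure so
    the full pipeline is testable end to end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    igraph,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
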