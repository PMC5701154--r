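Package: geneModules
Title: Derivation of Biological Modules from Disease-Gene Annotation Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving biological modules from a curated list of
    disease genes. Implements annotation enrichment against a background
    universe (one-sided hypergeometric test and the conservative EASE
    variant), construction of binary gene-by-annotation incidence matrices,
    Jaccard-distance Ward agglomerative clustering with a height-cut module
    definition, weighted term extraction for semantic cluster labelling,
    and a bipartite gene-pathway signalling-network analysis with
    percentile hub detection, bridge-gene identification, one-mode
    projection, and Louvain community detection with modularity. A
    synthetic-data generator with planted modules, hubs, and bridges
    supports end-to-end validation without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneSetEnrichment, Clustering, Network, GraphAndNetwork,
    Pathways, Software
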