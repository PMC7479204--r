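Package: tcmnet
Title: Bipartite Network Modeling and Community Validation for Traditional Chinese Medicine Herb-Ingredient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds herb-ingredient bipartite networks from incidence tables,
    extracts the giant component, projects the bipartite graph onto either
    node set with shared-neighbor edge weights (natural-product and
    ingredient similarity networks), detects communities by greedy
    agglomerative optimization of Newman-Girvan modularity, and validates
    that the detected communities are coherent with respect to external
    annotations (meridian and property label sets, SMILES strings compared
    by the Dice index over character bigrams, and protein-target sets)
    against a size-preserving random-grouping null with a Wilcoxon rank-sum
    test. A synthetic planted-block generator provides ground-truth
    benchmark data so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    mclust,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
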