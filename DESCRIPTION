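Package: crossdpcoa
Title: Crossed-Factor Double Principal Coordinate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordination and diversity partitioning for communities classified
    by two crossed factors. Builds the double principal coordinate analysis
    (DPCoA) space from any Euclidean species dissimilarity (phylogenetic,
    taxonomic or functional), partitions Rao's quadratic entropy into
    within-community, main-effect and interaction components (ANOQE), and
    visualises the conditional effect of one factor given the other through a
    mean-based re-centring scheme (version 1) and an orthogonal-complement
    projection scheme (version 2). Includes dissimilarity constructors from
    Newick phylogenies and taxonomies, readers and writers for community and
    design tables, and a synthetic-data generator for balanced factorial
    community data with tree-structured clade effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    vegan,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
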