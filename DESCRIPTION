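Package: tbnet
Title: Tree-Based Unrooted Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data structures and exact algorithms for unrooted binary
    phylogenetic networks, centred on tree-based networks: networks that
    contain a spanning tree (a support tree) whose leaves are exactly the
    taxon set. Provides validation and structural analysis (cut-edges,
    splits, properness, blob decomposition, level), exact recognition of
    tree-based, base-tree containment, displayed-tree and fully tree-based
    properties with support-tree witnesses, the correspondence between
    unrooted tree-based networks and rooted tree-based networks via edge
    orientation, the reduction from Hamiltonicity of cubic graphs, and
    generators and enumerators (cubic multigraph generators of simple
    level-k networks, random tree-based networks, unrooted binary trees)
    that allow the structural theory to be verified computationally at
    desk scale. Includes a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
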