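Package: treekit
Title: Scalable Loading, Traversal and Manipulation of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lightweight two-class tree data model (nodes and trees) for
    working with very large phylogenies. Reads Newick, NEXUS and NeXML from
    strings, plain-text files or gzip-compressed files; writes Newick;
    iterates nodes lazily in pre-order, in-order, post-order, level-order
    and root-distance order without recursion so trees with hundreds of
    thousands of leaves traverse comfortably; supports rerooting, pruning
    and subtree extraction; and computes summary statistics (height,
    average branch length, patristic distances, all-pairs leaf distance
    matrices, most recent common ancestors, treeness, the Gamma statistic)
    and Lineages-Through-Time series with ggplot2 rendering. Includes a
    reproducible random-tree generator (Yule, coalescent and
    random-attachment models) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    rlang,
    stats,
    tools,
    utils,
    xml2
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
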