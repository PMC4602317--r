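Package: sgtree
Title: Supertrees for Gene Families Minimizing Reconciliation Cost
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Combines rooted binary gene trees built on subsets of a gene
    family into a single supertree ("supergenetree") guided by a known
    species tree. Tests compatibility of the input trees with the BUILD
    algorithm over rooted triplets, constructs a supertree of minimum
    duplication or duplication-plus-loss (mutation) cost by an exact
    dynamic program over bipartitions of triplet-graph components, and
    provides a greedy heuristic that merges duplications preceding the
    first speciation by solving weighted Max-Cut instances recursively.
    Includes lowest-common-ancestor reconciliation with duplication and
    loss counts, a brute-force enumeration oracle over all rooted binary
    topologies, a gene-family simulator with known ground truth, and a
    graph-coloring reduction used as a correctness fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
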