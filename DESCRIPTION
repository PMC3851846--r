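Package: ancadj
Title: Ancestral Gene Adjacency Reconstruction from Reconciled Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral gene adjacencies along a dated species
    phylogeny from gene trees reconciled with duplication, loss and lateral
    transfer events. A dynamic program over pairs of gene subtrees minimises
    the weighted number of adjacency gains and breakages needed to explain
    the extant adjacencies, yielding one minimum-cost adjacency history per
    possible-homology class. Includes readers for annotated Newick
    reconciliations and adjacency tables, a forward simulator of gene and
    adjacency evolution with ground truth, an exhaustive small-instance
    oracle for validation, summaries of ancestral genome structure (gene
    degree distributions, adjacency-to-gene ratios) and detection of
    co-transferred and co-duplicated gene clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
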