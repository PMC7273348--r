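Package: blockevol
Title: Evolutionary Analysis of Bacterial Biosynthetic Gene Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of bacterial operons and other
    gene clusters ("gene blocks"), built around the gibberellin (GA)
    biosynthetic operon of plant-associated proteobacteria. The package
    assigns genome features to reference operon gene families from tabular
    homology-search hits (classifying full-length orthologs, pseudogenes and
    gene fusions), assembles orthologous gene blocks with a same-strand
    intergenic-distance neighbor rule, computes an event-based distance
    between blocks (deletions, duplications and splits), reconstructs
    ancestral gene blocks on a rooted phylogeny by maximum parsimony,
    builds neighbor-joining trees from marker-gene or concatenated-operon
    alignments, reduces taxon sets by greedy phylogenetic-diversity
    maximization, and screens for horizontal gene transfer with sliding-window
    GC-content contrasts. A seeded simulator of gene-block evolution along a
    birth-process tree (with deletion, duplication, split, gain, whole-operon
    transfer and pseudogenizing truncation, plus genome sequences with
    controlled GC structure) provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
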