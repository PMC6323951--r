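Package: paleogene
Title: Ancestral Gene and Genome Reconstruction from Reconciled Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconciles rooted gene family trees against a rooted, possibly
    multifurcating species tree, infers gene-loss events by maximum parsimony
    and represents every inferred ancestral gene and loss as an explicit tree
    node, reconstructs ancestral protein sequences by per-column plurality
    voting with nearest-outgroup tie-breaking, assembles ancestral genome gene
    sets with deterministic stable identifiers, duplication-aware protein
    naming and Gene Ontology term propagation, computes proxy genes (the
    least-diverged extant descendant of an ancestral gene in a chosen genome),
    and partitions an extant genome against any of its ancestors into
    inherited, lost, gained and untraced gene sets. A duplication-loss
    birth-death simulator with known ancestral truth supports validation of
    every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
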