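Package: phyloplace
Title: Maximum Likelihood Placement of Sequence Fragments into Fixed Reference Phylogenies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places anonymous nucleotide or peptide sequence fragments onto the
    branches of a fixed reference phylogeny by maximum likelihood under
    empirical amino-acid substitution models with discrete-Gamma rate
    heterogeneity, or by maximum parsimony. Provides the surrounding pipeline
    for metagenomic taxonomic binning: six-frame translation, profile
    alignment of query peptides to a reference alignment, conserved-block
    (Gblocks-style) column trimming, multi-marker concatenation, a
    candidate-branch bootstrap heuristic, jplace export, and a leave-one-out
    validation harness with node-distance and taxonomy-agreement scoring.
    A synthetic-data generator (random reference packages, sequence evolution
    along trees, planted queries) makes the whole pipeline testable without
    external reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
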