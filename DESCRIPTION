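Package: chromidFinder
Title: Identification of Chromids Among Bacterial Replicons and
    Metagenome-Assembled Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies bacterial replicons as chromosomes, chromids or
    other elements. Implements a complete-genome screen (longest replicon
    as chromosome; secondary replicons called chromids when their GC
    content is within one percentage point of the chromosome and they
    carry plasmid replication, plasmid partitioning and chromosomal core
    gene markers) and a pooled-sequence pipeline for metagenome-assembled
    genomes that clusters sequences around DnaA-bearing centers and
    filters cluster members by tetranucleotide relative-abundance
    distance. Ships strand-symmetrized k-mer signature computations, a
    pluggable marker scanner (exact-motif and profile-HMM backends), a
    seeded generator of synthetic multipartite genomes with ground-truth
    labels, and evaluation utilities (confusion matrices, accuracy,
    precision, TPR, FPR, threshold sweeps, ROC/PR points).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Metagenomics, Sequencing, Software
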