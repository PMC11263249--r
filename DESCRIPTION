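Package: mitocomp
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for comparative and phylogenetic analysis of circular
    fungal mitochondrial genomes. Reads annotated GenBank flat files, computes
    base-composition statistics (GC content, GC and AT skew), partitions
    genomes into coding, RNA, intron, accessory-ORF and intergenic regions,
    tabulates codon usage and relative synonymous codon usage (RSCU) with PCA
    clustering, estimates Kimura two-parameter distances and Nei-Gojobori
    Ka/Ks, detects dispersed and tandem repeats, maps cox1 group-I intron
    insertion-position classes (Pcls), compares circular gene orders by signed
    breakpoint distance, finds pairwise synteny blocks, and builds concatenated
    multi-gene datasets for neighbor-joining phylogenetics with bootstrap and
    parsimony scoring. Includes a seeded simulator of annotated circular
    mitogenomes with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    data.table,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
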