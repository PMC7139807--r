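Package: organellr
Title: Comparative Organelle Genomics: Repeats, Intracellular Gene
    Transfer, Gene Fission and Duplicate-Copy Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of plant organelle genomes and
    their traffic with the nuclear genome. Provides a seed-and-extend local
    nucleotide aligner with Karlin-Altschul E-values and two presets (a
    sensitive word-7 search for dispersed repeats and a fast word-28 search
    for inter-compartment shared DNA), non-redundant repeat quantification
    (tandem plus dispersed, overlaps excluded), quantification of DNA shared
    among nucleus, mitochondrion and plastid with detection of large
    contiguous organelle-derived blocks in nuclear chromosomes, detection of
    gene loss, pseudogenization, intron loss and deletion-induced gene
    fission against reference gene models, and distance-based phylogenies of
    labeled gene copies that classify organelle-to-nucleus functional
    transfers as single or repeated events. Seeded simulators generate
    genomes and gene-copy alignments with known truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
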