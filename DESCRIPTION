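Package: swingerseq
Title: Detection and Analysis of Systematic Nucleotide-Exchange (Swinger) RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the genomic template of sequence reads that fail
    canonical homology search by exhaustively testing the 23 bijective
    nucleotide exchanges ("swinger" transformations) of the DNA alphabet.
    Provides the permutation algebra of the exchanges, an affine-gap local
    aligner used to classify reads as canonical, swinger or unidentified,
    gene-model annotation (thirds compartmentalization and exon/intron
    structure), the associated statistics (exact one-tailed sign tests,
    abundance-length and conservation-abundance correlations), a seeded
    simulator of planted swinger reads, and packaged tables of published
    swinger EST assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
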