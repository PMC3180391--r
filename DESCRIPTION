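Package: vdga
Title: Vertical-Decomposition Genetic Algorithm for Protein Multiple
    Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aligns protein sequence families with a genetic algorithm that
    vertically decomposes candidate alignments into column blocks,
    re-aligns each block with a neighbour-joining guide tree, and keeps the
    reassembly when the weighted sum-of-pairs fitness improves. Includes
    affine-gap pairwise alignment, dynamic-programming and Kimura protein
    distances, CLUSTAL W sequence weights, a progressive profile aligner,
    FASTA/CLUSTAL/MSF alignment input and output, a synthetic
    protein-family simulator with known true alignments, and SPS/CS
    accuracy scoring against reference alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
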