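Package: mitedyn
Title: Comparative Dynamics of Miniature Transposable Element Families in
    Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the insertional dynamics of a miniature
    transposable element (MITE) family across a set of related genomes,
    modelled on allopolyploid wheat (diploid A and D donors, AB
    tetraploids, ABD hexaploid). Provides consensus-driven seed-and-extend
    retrieval of element copies with overlap deduplication, target site
    duplication (TSD) detection and sequence-logo summaries, flank-anchored
    cross-genome presence/absence classification with orthologous-locus
    clustering and Venn region counts, gene-proximity annotation,
    TN93/neighbor-joining phylogenies with bootstrap support, a
    chromosome-walking classifier of large genomic rearrangements
    (deletion, insertion/introgression, inversion, duplication), and a
    seeded allopolyploid genome simulator that plants element copies and
    rearrangements with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
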