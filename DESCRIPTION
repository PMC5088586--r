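Package: plastarch
Title: Comparative Architecture of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid (chloroplast) genome
    architecture. Reads annotated plastomes (FASTA plus GenBank-style feature
    tables or a simple TSV dialect, with GFF3 export), computes genome
    accounting (composition, coding/intron/intergenic partition), detects the
    large inverted repeat and derives the quadripartite map with junction
    comparisons, extracts shared signed gene orders and computes exact
    Hannenhalli-Pevzner reversal distances with sorting scenarios and
    rearrangement rates per 1,000 substitutions, finds maximal exact dispersed
    repeats (direct and inverted) with masked-coverage summaries, maintains an
    intron registry with insertion-site mapping onto reference coordinates and
    positional-homolog grouping, and analyses group IIA intron exon-binding
    site (EBS/IBS and delta) complementarity to classify intron-family spread
    as retrohoming-like versus retrotransposition-like. A deterministic
    synthetic-plastome simulator with recorded ground truth makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
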