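Package: srnakit
Title: Small RNA-Seq Read Classification, Quantification and piRNA
    Ping-Pong Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for single-end small RNA-seq libraries:
    length selection, exhaustive ungapped k-mismatch read placement on a set
    of multi-FASTA references, sequential classification of genome-mapping
    reads into miRNA/rRNA/tRNA/snRNA/transcript/transposable-element
    categories, extraction of the bonafide/miRNA/siRNA/piRNA subgroups,
    per-feature counting with RPKM and per-million-of-subgroup
    normalization, 1U/10A nucleotide-bias tables, mismatch-stratified
    transposable-element tables, strand-specific coverage tracks and
    bedgraph export, and the piRNA ping-pong signature: the spectrum of
    5'-overlaps between opposite-strand placements, with a z-score and
    p-value for the 10-nt overlap. Includes a deterministic synthetic-data
    simulator with a ground-truth manifest so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
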