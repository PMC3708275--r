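Package: cnspipe
Title: Conserved Non-Coding Sequence Discovery Between Annotated Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated discovery of conserved non-coding sequences (CNSs)
    between two annotated genomes. Implements the full pipeline: coverage-based
    repeat masking, cross-genome co-annotation of missed genes, quota-constrained
    syntenic block chaining over CDS anchors, sensitive seeded local alignment of
    paired gene spaces with a Karlin-Altschul bit-score acceptance threshold, a
    geometric (bow-tie) syntenic filter cascade, CNS-to-gene assignment and
    positional classification, Bigfoot gene calling, pan-species CNS
    intersection, and motif/term enrichment statistics. Includes a synthetic
    genome-pair generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
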