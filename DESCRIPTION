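Package: syntrace
Title: Gene Collinearity, Reciprocal-Best-Hit Homology, and Exon Structure
    Analysis for Small Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Traces the duplication origin of paralogs in small plant gene
    families from gene order, sequence homology, and gene architecture.
    Implements gene-neighborhood collinearity detection (windowed all-vs-all
    protein comparison, E-value homology matrices, diagonal chaining and
    high/weak/none calls), reciprocal-best-hit pairing and family census,
    alignment-derived percent-identity matrices and site-coverage column
    filtering, exon-structure conservation analysis, and a synthetic-genome
    simulator that plants tandem and segmental duplications with
    machine-readable truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
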