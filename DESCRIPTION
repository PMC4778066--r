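Package: srnamir
Title: Small RNA Sequencing Analysis of Nutrient-Stress-Responsive Plant miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small-RNA sequencing analysis pipeline for two-library
    (treatment vs control) plant miRNA studies: read cleaning and collapsing to
    unique tags, priority-cascade annotation against non-coding RNA, known-miRNA,
    repeat and gene-model references, hairpin-based novel miRNA prediction with a
    pluggable RNA secondary-structure folding engine, tags-per-million
    normalization with an exact conditional count test for differential
    expression, rule-based plant miRNA target prediction with wobble-weighted
    mismatch scoring, and qRT-PCR (ddCt) validation and direction-concordance
    reporting. A synthetic-data module generates toy genomes and paired sRNA
    libraries with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
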