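Package: senescmir
Title: Small RNA and PARE Degradome Analysis of Senescing Plant Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for small RNA and PARE (parallel analysis of
    RNA ends, degradome) sequencing across plant developmental senescence.
    Implements adapter trimming and collapsing of small RNA reads, exact-match
    genome placement, removal of structural RNA (tRNA/rRNA/sn/snoRNA) reads,
    transcripts-per-two-million (TP2M) normalization, perfect-match
    quantification of known miRNAs with a fold-change screen for
    senescence-regulated candidates, discovery of new senescence-inducible
    hairpin small RNA loci (fold-change filter, genomic clustering, strand
    bias, stem-loop folding, abundance reporting with MIRNA annotation
    criteria), plant-style miRNA target penalty scoring, and PARE-based
    validation of small RNA guided cleavage at the position 10/11 rule.
    Includes a fully synthetic data generator (genome, annotations,
    transcriptome, raw read libraries, truth ledger) so the entire pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    Rcpp,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
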