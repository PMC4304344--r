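#' Read and write sequence and annotation files
#'
#' Thin wrappers over Biostrings and rtracklayer keeping all disk formats in
#' one place: FASTA (genome, transcriptome, catalogs), FASTQ (raw reads,
#' Phred+33 with constant dummy qualities on write), GFF3 (annotations,
#' 1-based inclusive on disk, converted to/from the package's 0-based
#' half-open internal convention by the callers).
#'
#' @param path file path.
#' @param x named character vector of sequences (write_fasta/write_fastq) or
#'   a GRanges (write_gff3).
#' @return `read_fasta`/`read_fastq` return a named character vector;
#'   `read_gff3` returns a GRanges.
#' @name io
NULL

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @export
write_fastq <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(x)
  quals <- Biostrings::BStringSet(strrep("I", nchar(x)))
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' @rdname io
#' @export
read_gff3 <- function(path) rtracklayer::import(path, format = "gff3")

#' @rdname io
#' @export
write_gff3 <- function(x, path) {
  rtracklayer::export(x, path, format = "gff3")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
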