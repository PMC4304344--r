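#' Trim the 3' adapter from raw small RNA reads
#'
#' Finds the leftmost exact occurrence of the adapter's first `min_overlap`
#' bases and returns the prefix before it as the insert. Reads are rejected
#' when no adapter is found, when the insert length falls outside
#' `[min_len, max_len]`, or when the insert contains a non-ACGT character
#' (N-containing inserts cannot be exact-matched and are dropped here).
#'
#' @param reads character vector of raw reads.
#' @param adapter3 3' adapter sequence.
#' @param min_overlap minimum adapter prefix that must be present.
#' @param min_len,max_len allowed insert length range.
#' @return data.frame with columns `read`, `insert` (NA when rejected),
#'   `kept`, `reason` ("ok", "no_adapter", "too_short", "too_long",
#'   "non_acgt").
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 7L,
                         min_len = 18L, max_len = 30L) {
  stopifnot(min_overlap >= 1, min_len <= max_len,
            nchar(adapter3) >= min_overlap)
  key <- substr(rna_to_dna(adapter3), 1L, min_overlap)
  reads <- toupper(reads)
  pos <- as.integer(regexpr(key, reads, fixed = TRUE))
  insert <- ifelse(pos > 0, substr(reads, 1L, pos - 1L), NA_character_)
  len <- nchar(insert)
  reason <- rep("ok", length(reads))
  reason[pos < 0] <- "no_adapter"
  reason[pos > 0 & len < min_len] <- "too_short"
  reason[pos > 0 & len > max_len] <- "too_long"
  bad <- reason == "ok" & grepl("[^ACGT]", insert)
  reason[bad] <- "non_acgt"
  kept <- reason == "ok"
  insert[!kept] <- NA_character_
  data.frame(read = unname(reads), insert = unname(insert), kept = kept,
             reason = reason, stringsAsFactors = FALSE)
}

#' Collapse inserts to a distinct-sequence read set
#'
#' @param inserts character vector of trimmed inserts (one entry per read).
#' @param library_id,tissue,stage library metadata.
#' @return object of class `read_set`: data.frame `records` (sequence,
#'   count) plus metadata and provenance flags.
#' @export
collapse_reads <- function(inserts, library_id = "lib", tissue = NA_character_,
                           stage = NA_character_) {
  dt <- data.table::data.table(sequence = inserts)
  rec <- dt[, list(count = .N), by = "sequence"]
  data.table::setorder(rec, sequence)
  read_set(as.data.frame(rec), library_id, tissue, stage, trimmed = TRUE)
}

#' @rdname collapse_reads
#' @param records data.frame with `sequence` and `count` columns.
#' @param trimmed,genome_matched,structural_removed provenance flags.
#' @export
read_set <- function(records, library_id = "lib", tissue = NA_character_,
                     stage = NA_character_, trimmed = FALSE,
                     genome_matched = FALSE, structural_removed = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("sequence", "count") %in% names(records)))
  if (nrow(records)) {
    stopifnot(all(records$count >= 1), !anyDuplicated(records$sequence))
  }
  structure(list(records = records[, c("sequence", "count")],
                 library_id = library_id, tissue = tissue, stage = stage,
                 flags = c(trimmed = trimmed, genome_matched = genome_matched,
                           structural_removed = structural_removed)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set", x$library_id,
      sprintf("(%s/%s):", x$tissue, x$stage),
      nrow(x$records), "distinct,", sum(x$records$count), "reads; flags:",
      paste(names(x$flags)[x$flags], collapse = ","), "\n")
  invisible(x)
}

total_count <- function(rs) if (nrow(rs$records)) sum(rs$records$count) else 0L

#' Exact-match anchor index of a genome
#'
#' Hashes every genomic k-mer (default k = 18, the shortest retained
#' insert). A query of length >= k is located by anchoring its first k
#' bases (forward and reverse-complement probes for the two strands) and
#' verifying the full-length extension against the genome, so one index
#' serves all query lengths.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k anchor length.
#' @return object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 18L) {
  stopifnot(!is.null(names(genome)))
  structure(list(genome = genome, k = as.integer(k),
                 ptr = kmer_index_build(names(genome), unname(genome),
                                        as.integer(k))),
            class = "genome_index")
}

empty_hits <- function() {
  data.frame(sequence = character(), chrom = character(), start = integer(),
             end = integer(), strand = character())
}

# naive scan fallback for queries shorter than the anchor
scan_short <- function(seqs, genome) {
  out <- list()
  for (q in seqs) {
    rcq <- revcomp(q)
    for (ch in names(genome)) {
      for (std in c("+", "-")) {
        pat <- if (std == "+") q else rcq
        at <- gregexpr(pat, genome[[ch]], fixed = TRUE)[[1]]
        at <- at[at > 0]
        if (length(at))
          out[[length(out) + 1L]] <- data.frame(
            sequence = q, chrom = ch, start = at - 1L,
            end = at - 1L + nchar(q), strand = std,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty_hits()
}

#' Map sequences to the genome with no mismatches
#'
#' Returns all exact occurrences of each query on both strands, 0-based
#' half-open, deterministically ordered by (sequence, chrom, start, strand).
#' An empty result is valid (the sequence does not occur). Queries shorter
#' than the index anchor fall back to a direct scan.
#'
#' @param seqs character vector of query sequences (>= 15 nt).
#' @param genome named character vector (ignored when `index` is given).
#' @param index optional pre-built [genome_index()].
#' @return data.frame with columns `sequence`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
map_exact <- function(seqs, genome = NULL, index = NULL) {
  if (is.null(index)) index <- genome_index(genome)
  seqs <- unique(toupper(seqs))
  if (!length(seqs)) return(empty_hits())
  stopifnot(all(nchar(seqs) >= 15))
  k <- index$k
  short <- seqs[nchar(seqs) < k]
  seqs <- seqs[nchar(seqs) >= k]
  parts <- list()
  if (length(short)) parts[[1L]] <- scan_short(short, index$genome)
  if (length(seqs)) {
    hit <- kmer_index_map(index$ptr, seqs)
    if (nrow(hit)) {
      parts[[length(parts) + 1L]] <- data.frame(
        sequence = seqs[hit$query],
        chrom = names(index$genome)[hit$chrom],
        start = hit$start,
        end = hit$start + nchar(seqs)[hit$query],
        strand = ifelse(hit$minus, "-", "+"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(parts)) do.call(rbind, parts) else empty_hits()
  if (!nrow(out)) return(empty_hits())
  out <- out[order(out$sequence, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Keep reads with at least one perfect genome match
#'
#' @param readset a `read_set`.
#' @param hits data.frame from [map_exact()] covering the read set.
#' @return list with `retained` (read_set, genome_matched flag set) and
#'   `unmatched_count` (reads dropped).
#' @export
filter_genome_matched <- function(readset, hits) {
  keep <- readset$records$sequence %in% hits$sequence
  retained <- read_set(readset$records[keep, , drop = FALSE],
                       readset$library_id, readset$tissue, readset$stage,
                       trimmed = readset$flags[["trimmed"]],
                       genome_matched = TRUE)
  list(retained = retained,
       unmatched_count = sum(readset$records$count[!keep]))
}

structural_types <- c("tRNA", "rRNA", "snoRNA", "snRNA")
known_feature_types <- c(structural_types, "gene", "mRNA", "transcript",
                         "miRNA", "exon")

#' Remove structural-RNA reads by annotation overlap
#'
#' A distinct sequence is removed when any of its genome hits overlaps (by
#' at least 1 nt, strand-agnostic) an annotated tRNA, rRNA, snoRNA or snRNA
#' interval. Counts are conserved: retained + structural = input.
#' Annotation features of unknown type are ignored with a warning.
#'
#' @param readset a genome-matched `read_set`.
#' @param hits data.frame from [map_exact()] covering every distinct
#'   sequence of the read set.
#' @param annotations GRanges with a `type` metadata column (1-based
#'   inclusive, GFF3 convention).
#' @return list with `retained` (read_set), `structural` (read_set of
#'   removed sequences) and `structural_count` (reads removed).
#' @export
filter_structural <- function(readset, hits, annotations) {
  types <- as.character(annotations$type)
  unknown <- setdiff(unique(types), known_feature_types)
  if (length(unknown))
    warning("ignoring annotation intervals of unknown type: ",
            paste(unknown, collapse = ", "))
  struct <- annotations[types %in% structural_types]
  seqs <- readset$records$sequence
  if (length(struct) && nrow(hits)) {
    h <- hits[hits$sequence %in% seqs, , drop = FALSE]
    hg <- GenomicRanges::GRanges(h$chrom,
                                 IRanges::IRanges(h$start + 1L, h$end))
    ov <- GenomicRanges::findOverlaps(hg, struct, minoverlap = 1L,
                                      ignore.strand = TRUE)
    bad <- unique(h$sequence[S4Vectors::queryHits(ov)])
  } else bad <- character(0)
  is_bad <- seqs %in% bad
  mk <- function(rows) read_set(
    readset$records[rows, , drop = FALSE], readset$library_id,
    readset$tissue, readset$stage, trimmed = readset$flags[["trimmed"]],
    genome_matched = readset$flags[["genome_matched"]],
    structural_removed = TRUE)
  list(retained = mk(!is_bad), structural = mk(is_bad),
       structural_count = sum(readset$records$count[is_bad]))
}

#' Normalize a read set to transcripts per N
#'
#' abundance(seq) = count(seq) / total retained count * scale. The default
#' scale, 2e6, is transcripts per two million (TP2M); 1e7 gives the TP10M
#' unit used for locus abundance tables.
#'
#' @param readset a retained `read_set`.
#' @param scale normalization total.
#' @return data.frame with `sequence`, `count`, `tp`.
#' @export
normalize_abundance <- function(readset, scale = 2e6) {
  tot <- total_count(readset)
  if (tot == 0) stop("cannot normalize an empty read set")
  data.frame(sequence = readset$records$sequence,
             count = readset$records$count,
             tp = readset$records$count / tot * scale,
             stringsAsFactors = FALSE)
}

#' Build a distinct-sequence abundance matrix across libraries
#'
#' @param readsets list of retained `read_set` objects.
#' @param scale normalization total per library.
#' @return numeric matrix (rows: sequences, columns: library ids) with a
#'   `library_info` attribute (data.frame: library_id, tissue, stage).
#' @export
abundance_matrix <- function(readsets, scale = 2e6) {
  ids <- vapply(readsets, `[[`, character(1), "library_id")
  stopifnot(!anyDuplicated(ids))
  norms <- lapply(readsets, normalize_abundance, scale = scale)
  seqs <- sort(unique(unlist(lapply(norms, `[[`, "sequence"))))
  m <- matrix(0, nrow = length(seqs), ncol = length(ids),
              dimnames = list(seqs, ids))
  for (i in seq_along(norms))
    m[norms[[i]]$sequence, i] <- norms[[i]]$tp
  attr(m, "library_info") <- data.frame(
    library_id = ids,
    tissue = vapply(readsets, function(r) as.character(r$tissue), character(1)),
    stage = vapply(readsets, function(r) as.character(r$stage), character(1)),
    stringsAsFactors = FALSE)
  m
}

#' Per-library processing statistics and size-class histogram
#'
#' @param raw_trimmed reads surviving adapter trimming.
#' @param genome_matched reads with at least one perfect genome hit.
#' @param structural_count reads removed as structural RNA.
#' @param retained the final retained `read_set`.
#' @param scale normalization total for the size histogram.
#' @return one-row data.frame of counts plus a `size_histogram` attribute
#'   (named numeric, normalized abundance per insert length).
#' @export
library_stats <- function(raw_trimmed, genome_matched, structural_count,
                          retained, scale = 2e6) {
  norm <- normalize_abundance(retained, scale)
  hist <- tapply(norm$tp, nchar(norm$sequence), sum)
  out <- data.frame(library_id = retained$library_id,
                    tissue = retained$tissue, stage = retained$stage,
                    raw_trimmed = raw_trimmed,
                    genome_matched = genome_matched,
                    distinct = nrow(retained$records),
                    structural = structural_count,
                    retained = total_count(retained),
                    stringsAsFactors = FALSE)
  attr(out, "size_histogram") <- stats::setNames(as.numeric(hist), names(hist))
  out
}

#' Process one raw small RNA library end to end
#'
#' Trim, collapse, exact-map, drop unmatched and structural reads, and
#' tally the count-conservation accounting (raw = kept + rejected;
#' genome-matched = structural + retained).
#'
#' @param raw_reads character vector of raw reads.
#' @param index a [genome_index()].
#' @param annotations annotation GRanges.
#' @param adapter3 3' adapter.
#' @param library_id,tissue,stage metadata.
#' @param min_overlap,min_len,max_len trimming parameters.
#' @return list with `retained` (read_set), `stats` (library_stats row),
#'   `hits` (map of retained + structural sequences), `accounting`.
#' @export
process_srna_library <- function(raw_reads, index, annotations, adapter3,
                                 library_id = "lib", tissue = NA, stage = NA,
                                 min_overlap = 7L, min_len = 18L,
                                 max_len = 30L) {
  tr <- trim_adapter(raw_reads, adapter3, min_overlap, min_len, max_len)
  rs <- collapse_reads(tr$insert[tr$kept], library_id, tissue, stage)
  hits <- map_exact(rs$records$sequence, index = index)
  gm <- filter_genome_matched(rs, hits)
  fs <- filter_structural(gm$retained, hits, annotations)
  stats_row <- library_stats(
    raw_trimmed = sum(tr$kept),
    genome_matched = total_count(gm$retained),
    structural_count = fs$structural_count,
    retained = fs$retained)
  acct <- c(raw = length(raw_reads), trimmed_kept = sum(tr$kept),
            trimmed_rejected = sum(!tr$kept),
            genome_matched = total_count(gm$retained),
            unmatched = gm$unmatched_count,
            structural = fs$structural_count,
            retained = total_count(fs$retained))
  list(retained = fs$retained, stats = stats_row, hits = hits,
       accounting = acct)
}
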