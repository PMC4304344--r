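#' Candidate sequences for new senescence-inducible loci
#'
#' Distinct retained sequences that are not identical to any catalog mature,
#' exceed the abundance floor in at least one library of the tissue, and are
#' elevated `fold` or more in the early or late senescence library relative
#' to mature (same pseudocount convention as the miRNA screen).
#'
#' @param mat distinct-sequence abundance matrix (TP2M).
#' @param catalog miRNA catalog data.frame.
#' @param tissue tissue driving the filter (the published filter uses leaf).
#' @param fold,floor,pseudocount filter parameters.
#' @param library_info optional design override.
#' @return character vector of candidate sequences.
#' @export
candidate_sequences <- function(mat, catalog, tissue = "leaf", fold = 3,
                                floor = 50, pseudocount = 1,
                                library_info = NULL) {
  info <- library_info %||% attr(mat, "library_info")
  cols <- vapply(c("mature", "early_senescence", "late_senescence"),
                 function(st) stage_column(info, tissue, st), character(1))
  tcols <- info$library_id[info$tissue == tissue]
  a <- mat[, cols, drop = FALSE]
  passed <- apply(mat[, tcols, drop = FALSE] > floor, 1, any)
  fc_e <- (a[, 2] + pseudocount) / (a[, 1] + pseudocount)
  fc_l <- (a[, 3] + pseudocount) / (a[, 1] + pseudocount)
  keep <- passed & (fc_e >= fold | fc_l >= fold) &
    !(rownames(mat) %in% catalog$sequence)
  rownames(mat)[keep]
}

#' Cluster candidate hits into windows and apply the strand-bias filter
#'
#' Candidate genome hits are expanded by `flank` on both sides and merged
#' when within `merge_gap`. For each window the strand bias is computed
#' over the abundance mass of ALL retained sequences hitting the window
#' (not only candidates): bias = max(plus, minus) / total. Windows with
#' bias strictly greater than `min_bias` are kept. A multi-mapping
#' sequence contributes its full mass at every hit.
#'
#' @param candidates character vector from [candidate_sequences()].
#' @param hits data.frame from [map_exact()] covering all retained
#'   sequences.
#' @param mass named numeric: total abundance mass per retained sequence
#'   (e.g. TP2M summed over the tissue's libraries).
#' @param flank window expansion around each hit (nt).
#' @param merge_gap merge windows separated by at most this many nt.
#' @param min_bias strand-bias threshold (exclusive).
#' @return data.frame of windows: `chrom`, `start` (0-based), `end`
#'   (half-open), `strand_bias`, `majority_strand`, `n_candidates`,
#'   `mass`, `kept`.
#' @export
cluster_and_bias <- function(candidates, hits, mass, flank = 250L,
                             merge_gap = 100L, min_bias = 0.9) {
  ch <- hits[hits$sequence %in% candidates, , drop = FALSE]
  skipped <- setdiff(candidates, ch$sequence)
  if (length(skipped))
    message(length(skipped), " candidate(s) without genome hits skipped")
  if (!nrow(ch))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand_bias = numeric(),
                      majority_strand = character(), n_candidates = integer(),
                      mass = numeric(), kept = logical()))
  # cluster the candidate hits themselves, then attach the flanks; flanking
  # before merging would chain unrelated clusters across a compact genome
  cg <- GenomicRanges::GRanges(ch$chrom,
                               IRanges::IRanges(ch$start + 1L, ch$end))
  win <- GenomicRanges::reduce(cg, min.gapwidth = merge_gap)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(win),
    IRanges::IRanges(pmax(GenomicRanges::start(win) - flank, 1L),
                     GenomicRanges::end(win) + flank))
  hg <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  ov <- GenomicRanges::findOverlaps(hg, win, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- lapply(seq_along(win), function(w) {
    rows <- qh[sh == w]
    m <- mass[hits$sequence[rows]]
    m[is.na(m)] <- 0
    plus <- sum(m[hits$strand[rows] == "+"])
    minus <- sum(m[hits$strand[rows] == "-"])
    tot <- plus + minus
    bias <- if (tot > 0) max(plus, minus) / tot else NA_real_
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(win))[w],
      start = GenomicRanges::start(win)[w] - 1L,
      end = GenomicRanges::end(win)[w],
      strand_bias = bias,
      majority_strand = if (!is.na(bias) && minus > plus) "-" else "+",
      n_candidates = length(unique(
        hits$sequence[rows][hits$sequence[rows] %in% candidates])),
      mass = tot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$kept <- !is.na(out$strand_bias) & out$strand_bias > min_bias
  out
}

#' Exact maximum base-pairing count (Nussinov dynamic programming)
#'
#' Maximum number of Watson-Crick + G:U pairs over all nested (pseudoknot-
#' free) secondary structures with a minimum hairpin loop of `min_loop`
#' unpaired bases. This is the classic base-pair maximization recursion
#' including bifurcation.
#'
#' @param seq nucleotide sequence (RNA or DNA).
#' @param min_loop minimum unpaired bases enclosed by any pair.
#' @return integer pair count.
#' @export
nussinov_pairs <- function(seq, min_loop = 3L) {
  nussinov_pairs_cpp(rna_to_dna(seq), as.integer(min_loop))
}

#' Score the stem-loop (hairpin) capability of a sequence
#'
#' Automated replacement for manual fold inspection: finds the best single
#' stem-loop structure (nested pairs, no multiloop branching) where each
#' unpaired base inside the stem costs `lambda`, the hairpin loop and the
#' bases outside the stem are free, and the stem must span at least
#' `min_span` nt. The score is 2 * (pairs - lambda * unpaired) / span, in
#' [0, 1]: a near-perfect inverted repeat approaches 1, random sequence
#' rarely exceeds 0.5. Invariant under reverse complement.
#'
#' @param seq window sequence, at least 50 nt.
#' @param min_loop minimum hairpin loop size.
#' @param threshold pass threshold on the score.
#' @param lambda penalty per unpaired base inside the stem.
#' @param min_span minimum stem span (nt).
#' @return object of class `hairpin_report`: list with `score`, `pairs`,
#'   `stem_start`, `stem_end`, `loop_start`, `loop_end` (1-based in the
#'   window), `passes`.
#' @export
fold_hairpin <- function(seq, min_loop = 3L, threshold = 0.6,
                         lambda = 1.25, min_span = 50L) {
  seq <- rna_to_dna(seq)
  if (nchar(seq) < 50) stop("hairpin folding needs a sequence of >= 50 nt")
  r <- stem_fold_cpp(seq, as.integer(min_loop), lambda, as.integer(min_span))
  r$passes <- r$score >= threshold
  r$threshold <- threshold
  r$length <- nchar(seq)
  class(r) <- "hairpin_report"
  r
}

#' @export
print.hairpin_report <- function(x, ...) {
  cat(sprintf(
    "hairpin_report: score %.3f (%s), %d pairs, stem %d-%d, loop %d-%d\n",
    x$score, if (x$passes) "passes" else "fails", x$pairs,
    x$stem_start, x$stem_end, x$loop_start, x$loop_end))
  invisible(x)
}

# group locus member sequences into coterminal clusters: same strand and
# both ends within +/- tol nt
coterminal_clusters <- function(members, tol = 1L) {
  n <- nrow(members)
  cl <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (members$strand[i] == members$strand[j] &&
          abs(members$start[i] - members$start[j]) <= tol &&
          abs(members$end[i] - members$end[j]) <= tol)
        cl[cl == cl[j]] <- cl[i]
    }
  }
  match(cl, unique(cl))
}

#' Report a discovered locus: abundant sRNAs, track, annotation criteria
#'
#' Lists the locus's distinct sRNAs with abundance (summed across all
#' libraries, at the requested per-N scale) at or above the floor, emits a
#' per-position abundance track, and evaluates the precise-excision
#' criterion used for formal MIRNA annotation: precision = (mass of the two
#' most abundant coterminal sequence groups, one per hairpin arm when arm
#' assignment is available) / total locus mass, passing at
#' `precision_threshold`. Sequence ends within 1 nt are grouped as one
#' coterminal variant.
#'
#' @param window one row of the [cluster_and_bias()] result (or a list with
#'   `chrom`, `start`, `end`).
#' @param mat distinct-sequence abundance matrix (TP2M).
#' @param hits data.frame from [map_exact()] for all retained sequences.
#' @param hairpin optional `hairpin_report` for the folded subwindow (plus
#'   `fold_offset`, the window-relative 0-based offset of the folded
#'   sequence) used to assign arms.
#' @param abundance_floor minimum summed abundance (at `scale` units) for
#'   the abundant-sRNA table.
#' @param scale per-N unit of the report (default 1e7: TP10M, the unit of
#'   the published locus table; the matrix's TP2M values are rescaled).
#' @param precision_threshold pass threshold for the annotation criterion.
#' @param end_tolerance coterminal grouping tolerance (nt).
#' @return object of class `locus_report`: list with `srnas` (data.frame:
#'   sequence, rna, size, abundance), `track` (per-position abundance),
#'   `precision`, `passes_meyers`, `members`.
#' @export
report_locus <- function(window, mat, hits, hairpin = NULL,
                         abundance_floor = 1000, scale = 1e7,
                         precision_threshold = 0.75, end_tolerance = 1L) {
  h <- hits[hits$chrom == window$chrom & hits$start >= window$start &
              hits$end <= window$end, , drop = FALSE]
  h <- h[h$sequence %in% rownames(mat), , drop = FALSE]
  total_ab <- rowSums(mat[h$sequence, , drop = FALSE]) * scale / 2e6
  members <- data.frame(sequence = h$sequence, start = h$start, end = h$end,
                        strand = h$strand, abundance = unname(total_ab),
                        stringsAsFactors = FALSE)
  # one row per distinct sequence for the abundance table
  ab <- members[!duplicated(members$sequence), , drop = FALSE]
  ab <- ab[order(-ab$abundance, ab$sequence), , drop = FALSE]
  srnas <- data.frame(sequence = ab$sequence, rna = dna_to_rna(ab$sequence),
                      size = nchar(ab$sequence), abundance = ab$abundance,
                      stringsAsFactors = FALSE)
  srnas <- srnas[srnas$abundance >= abundance_floor, , drop = FALSE]
  rownames(srnas) <- NULL
  # per-position track over the window
  len <- window$end - window$start
  track <- numeric(len)
  for (r in seq_len(nrow(members))) {
    i0 <- members$start[r] - window$start + 1L
    i1 <- members$end[r] - window$start
    track[i0:i1] <- track[i0:i1] + members$abundance[r]
  }
  track <- data.frame(pos = window$start + seq_len(len) - 1L,
                      abundance = track)
  # precise-excision precision
  precision <- NA_real_
  passes <- NA
  if (nrow(members)) {
    cl <- coterminal_clusters(members, end_tolerance)
    cmass <- tapply(members$abundance, cl, sum)
    if (!is.null(hairpin)) {
      loop_mid <- (hairpin$loop_start + hairpin$loop_end) / 2 +
        (window$fold_offset %||% 0)
      arm <- ifelse((members$start - window$start) + nchar(members$sequence) / 2
                    <= loop_mid, "5p", "3p")
      top <- vapply(c("5p", "3p"), function(a) {
        am <- tapply(members$abundance[arm == a], cl[arm == a], sum)
        if (length(am)) max(am) else 0
      }, numeric(1))
      topmass <- sum(top)
    } else {
      topmass <- sum(sort(cmass, decreasing = TRUE)[1:min(2, length(cmass))])
    }
    precision <- topmass / sum(members$abundance)
    passes <- precision >= precision_threshold
  }
  structure(list(window = window, srnas = srnas, track = track,
                 precision = unname(precision),
                 passes_meyers = unname(passes), members = members),
            class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("locus_report %s:%d-%d: %d abundant sRNAs, precision %.3f (%s)\n",
              x$window$chrom, x$window$start, x$window$end, nrow(x$srnas),
              x$precision,
              if (isTRUE(x$passes_meyers)) "passes" else "fails"))
  if (nrow(x$srnas)) print(x$srnas[, c("rna", "size", "abundance")])
  invisible(x)
}

#' Discover senescence-inducible hairpin small RNA loci
#'
#' Full discovery path: candidate filter (not in the catalog, induced in
#' senescing leaf), genomic clustering with the strand-bias test, stem-loop
#' folding of the read-covered subwindow, and abundance reporting. A locus
#' is reported when it passes strand bias and the hairpin test and retains
#' at least one abundant sRNA above the floor.
#'
#' @param mat distinct-sequence abundance matrix (TP2M) over all libraries.
#' @param catalog miRNA catalog.
#' @param hits hits for all retained sequences.
#' @param genome named character vector of chromosome sequences.
#' @param tissue tissue driving the candidate filter.
#' @param fold,floor,pseudocount candidate filter parameters.
#' @param flank,merge_gap,min_bias clustering parameters.
#' @param fold_pad padding around the read-covered span that is folded.
#' @param min_loop,hairpin_threshold,lambda,min_span folding parameters.
#' @param abundance_floor,scale,precision_threshold reporting parameters.
#' @return object of class `discovery_result`: list with `loci` (data.frame
#'   of reported loci), `reports` (list of `locus_report`), `windows` (all
#'   windows with their filter outcomes).
#' @export
discover_loci <- function(mat, catalog, hits, genome, tissue = "leaf",
                          fold = 3, floor = 50, pseudocount = 1,
                          flank = 250L, merge_gap = 100L, min_bias = 0.9,
                          fold_pad = 30L, min_loop = 3L,
                          hairpin_threshold = 0.6, lambda = 1.25,
                          min_span = 50L, abundance_floor = 1000,
                          scale = 1e7, precision_threshold = 0.75) {
  info <- attr(mat, "library_info")
  cands <- candidate_sequences(mat, catalog, tissue, fold, floor, pseudocount)
  tcols <- info$library_id[info$tissue == tissue]
  mass <- rowSums(mat[, tcols, drop = FALSE])
  windows <- cluster_and_bias(cands, hits, mass, flank, merge_gap, min_bias)
  reports <- list()
  rows <- list()
  for (w in which(windows$kept)) {
    win <- windows[w, ]
    # fold the read-covered span (plus a small pad), not the full flanked
    # window: the flanks carry no reads and would dilute the stem score
    wh <- hits[hits$chrom == win$chrom & hits$start >= win$start &
                 hits$end <= win$end, , drop = FALSE]
    wh <- wh[wh$sequence %in% rownames(mat), , drop = FALSE]
    if (!nrow(wh)) next
    clen <- nchar(genome[[win$chrom]])
    f0 <- max(min(wh$start) - fold_pad, 0L)
    f1 <- min(max(wh$end) + fold_pad, clen)
    if (f1 - f0 < 50) {
      pad <- 50 - (f1 - f0)
      f0 <- max(f0 - ceiling(pad / 2), 0L)
      f1 <- min(f1 + ceiling(pad / 2), clen)
    }
    sub <- substr(genome[[win$chrom]], f0 + 1L, f1)
    # fold the transcribed (majority) strand: G:U wobble makes the stem
    # score strand-dependent
    if (win$majority_strand == "-") sub <- revcomp(sub)
    hp <- fold_hairpin(sub, min_loop, hairpin_threshold, lambda, min_span)
    if (!hp$passes) next
    if (win$majority_strand == "-") {  # map loop back to plus coordinates
      n <- f1 - f0
      ls <- n - hp$loop_end + 1L
      hp$loop_end <- n - hp$loop_start + 1L
      hp$loop_start <- ls
    }
    win$fold_offset <- f0 - win$start
    rep <- report_locus(win, mat, hits, hairpin = hp,
                        abundance_floor = abundance_floor, scale = scale,
                        precision_threshold = precision_threshold)
    rep$hairpin <- hp
    if (!nrow(rep$srnas)) next
    reports[[length(reports) + 1L]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = win$chrom, start = win$start, end = win$end,
      strand_bias = win$strand_bias, majority_strand = win$majority_strand,
      hairpin_score = hp$score, n_abundant = nrow(rep$srnas),
      top_srna = rep$srnas$sequence[1], precision = rep$precision,
      passes_meyers = rep$passes_meyers, stringsAsFactors = FALSE)
  }
  loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand_bias = numeric(), majority_strand = character(),
               hairpin_score = numeric(), n_abundant = integer(),
               top_srna = character(), precision = numeric(),
               passes_meyers = logical())
  structure(list(loci = loci, reports = reports, windows = windows,
                 candidates = cands),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("discovery_result:", length(x$candidates), "candidate sequences,",
      nrow(x$windows), "windows,", nrow(x$loci), "reported loci\n")
  if (nrow(x$loci)) print(x$loci)
  invisible(x)
}

#' Export discovered loci as BED6
#'
#' 0-based half-open; score column = strand bias * 1000.
#'
#' @param loci `loci` data.frame from [discover_loci()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start, loci$end,
                    sprintf("locus%02d", seq_len(nrow(loci))),
                    as.integer(round(loci$strand_bias * 1000)),
                    loci$majority_strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
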