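#' Build PARE 5'-end profiles over a transcriptome
#'
#' Collapses the 20-nt PARE tags, places them on transcripts by exact
#' sense-strand match (PARE fragments derive from mRNA, so matching is done
#' in transcript space), and increments the count at each match's 5'
#' position; a tag matching several transcripts increments each.
#' Normalization is per `scale` transcript-mapped reads (default 1e7,
#' echoing the TP10M unit).
#'
#' @param reads character vector of 20-nt PARE tags (or a `read_set`).
#' @param transcriptome named character vector of transcript sequences.
#' @param library_id,stage metadata.
#' @param scale normalization total.
#' @return object of class `pare_profiles`: list with `profiles` (long
#'   data.frame: transcript_id, pos, count, norm), `stats` (raw, mapped,
#'   distinct counts), `mapped_total`, `library_id`, `stage`.
#' @export
build_pare_profiles <- function(reads, transcriptome, library_id = "pare",
                                stage = NA_character_, scale = 1e7) {
  rs <- if (inherits(reads, "read_set")) reads else
    collapse_reads(toupper(reads), library_id, stage = stage)
  tx_index <- genome_index(transcriptome)
  hits <- map_exact(rs$records$sequence, index = tx_index)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  cnt <- rs$records$count[match(hits$sequence, rs$records$sequence)]
  mapped_seqs <- unique(hits$sequence)
  mapped_total <- sum(cnt)  # multi-transcript tags count at each match
  if (nrow(hits)) {
    dt <- data.table::data.table(transcript_id = hits$chrom,
                                 pos = hits$start + 1L, count = cnt)
    prof <- dt[, list(count = sum(count)), by = c("transcript_id", "pos")]
    data.table::setorder(prof, transcript_id, pos)
    prof <- as.data.frame(prof)
    prof$norm <- prof$count / mapped_total * scale
  } else {
    prof <- data.frame(transcript_id = character(), pos = integer(),
                       count = integer(), norm = numeric())
  }
  structure(list(profiles = prof,
                 stats = data.frame(
                   library_id = rs$library_id, stage = rs$stage,
                   raw = total_count(rs),
                   mapped = sum(rs$records$count[rs$records$sequence %in%
                                                   mapped_seqs]),
                   distinct = length(mapped_seqs), stringsAsFactors = FALSE),
                 mapped_total = mapped_total, library_id = rs$library_id,
                 stage = rs$stage, scale = scale),
            class = "pare_profiles")
}

#' @export
print.pare_profiles <- function(x, ...) {
  cat("pare_profiles", x$library_id, sprintf("(%s):", x$stage),
      x$stats$raw, "tags,", x$stats$mapped, "transcript-mapped,",
      x$stats$distinct, "distinct\n")
  invisible(x)
}

profile_vector <- function(profiles, transcript_id, what = "count") {
  p <- profiles$profiles
  p <- p[p$transcript_id == transcript_id, , drop = FALSE]
  stats::setNames(p[[what]], p$pos)
}

#' Validate predicted cleavage against a PARE profile
#'
#' The expected 5'-end position is the target base paired to sRNA position
#' 10 (the phosphodiester bond between the bases opposite sRNA positions
#' 10 and 11); `window` = w additionally accepts positions within +/- w nt.
#' The verdict is "supported" when the accepted positions carry nonzero
#' abundance and the best accepted position ranks at most `rank_max` among
#' the transcript's 5'-end positions. Rank and positivity are scale-free,
#' so the verdict is invariant to library depth.
#'
#' @param alignment a `target_alignment`-like object or one row of
#'   [predict_targets()] (needs `transcript_id` and `cleavage_pos`).
#' @param profiles a [build_pare_profiles()] object.
#' @param window acceptance window around the expected site (nt).
#' @param rank_max maximum rank of the site within the transcript.
#' @return object of class `cleavage_evidence`: list with `transcript_id`,
#'   `expected_pos`, `observed`, `site_rank`, `fraction`, `supported`.
#' @export
validate_cleavage <- function(alignment, profiles, window = 0L,
                              rank_max = 5L) {
  tx <- alignment$transcript_id
  site <- alignment$cleavage_pos
  v <- profile_vector(profiles, tx)
  accept <- as.character(seq(site - window, site + window))
  obs <- v[accept]
  obs[is.na(obs)] <- 0
  observed <- max(obs)
  total <- sum(v)
  rank <- if (observed > 0) 1L + sum(v > observed) else NA_integer_
  supported <- observed > 0 && !is.na(rank) && rank <= rank_max
  structure(list(transcript_id = tx, expected_pos = site, window = window,
                 observed = unname(observed),
                 observed_sum = unname(sum(obs)),
                 site_rank = rank,
                 fraction = if (total > 0) unname(sum(obs)) / total else NA_real_,
                 supported = supported),
            class = "cleavage_evidence")
}

#' @export
print.cleavage_evidence <- function(x, ...) {
  cat(sprintf(
    "cleavage_evidence %s@%d: %s (count %g, rank %s, fraction %.3f)\n",
    x$transcript_id, x$expected_pos,
    if (x$supported) "supported" else "unsupported", x$observed,
    ifelse(is.na(x$site_rank), "-", x$site_rank), x$fraction))
  invisible(x)
}

#' Track cleavage-site abundance across senescence stages
#'
#' Tabulates the normalized PARE abundance at each predicted site per
#' library, and annotates the monotone trend across the stage order by the
#' Spearman rank correlation of site abundance with stage rank
#' ("increasing" when rho >= `rho_min`, "decreasing" when <= -`rho_min`,
#' otherwise "none").
#'
#' @param alignments data.frame of predicted targets (rows with
#'   `transcript_id`, `cleavage_pos`).
#' @param profiles_by_library named list of [build_pare_profiles()] objects
#'   (>= 2 stages).
#' @param stage_order stage levels in developmental order.
#' @param rho_min trend threshold on |rho|.
#' @param window acceptance window around each site.
#' @return list with `table` (long data.frame: transcript_id, cleavage_pos,
#'   library_id, stage, abundance) and `trends` (per site: rho, trend).
#' @export
track_site_across_stages <- function(alignments, profiles_by_library,
                                     stage_order = senescence_stages(),
                                     rho_min = 0.5, window = 0L) {
  stages <- vapply(profiles_by_library, `[[`, character(1), "stage")
  if (length(unique(stages)) < 2) stop("need profiles from >= 2 stages")
  rows <- list()
  for (a in seq_len(nrow(alignments))) {
    tx <- alignments$transcript_id[a]
    site <- alignments$cleavage_pos[a]
    for (li in seq_along(profiles_by_library)) {
      p <- profiles_by_library[[li]]
      v <- profile_vector(p, tx, "norm")
      obs <- v[as.character(seq(site - window, site + window))]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, cleavage_pos = site,
        library_id = p$library_id, stage = p$stage,
        abundance = sum(obs, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$transcript_id, tab$cleavage_pos)
  trends <- lapply(split(tab, key), function(d) {
    sr <- match(d$stage, stage_order)
    rho <- if (stats::sd(d$abundance) == 0 || stats::sd(sr) == 0) 0 else
      suppressWarnings(stats::cor(sr, d$abundance, method = "spearman"))
    data.frame(transcript_id = d$transcript_id[1],
               cleavage_pos = d$cleavage_pos[1], rho = rho,
               trend = if (is.na(rho)) "none" else if (rho >= rho_min)
                 "increasing" else if (rho <= -rho_min) "decreasing"
               else "none",
               stringsAsFactors = FALSE)
  })
  trends <- do.call(rbind, trends)
  rownames(trends) <- NULL
  list(table = tab, trends = trends)
}
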