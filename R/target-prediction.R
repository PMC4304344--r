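#' Scoring constants for plant small RNA target prediction
#'
#' The penalty scheme of plant miRNA target prediction: mismatch 1.0, G:U
#' wobble 0.5, each bulged nucleotide 2.0, all doubled at positions 2-13
#' from the sRNA 5' end. Bulges are limited to `max_bulges` nucleotides and
#' forbidden opposite positions 10-11 so the cleavage register stays
#' unambiguous.
#'
#' @param mismatch,gu,bulge per-event penalties.
#' @param core core interval (positions from the sRNA 5' end).
#' @param core_mult penalty multiplier inside the core.
#' @param max_bulges maximum total bulged nucleotides per alignment.
#' @param protect positions opposite which bulges are forbidden.
#' @return list of constants.
#' @export
target_score_params <- function(mismatch = 1, gu = 0.5, bulge = 2,
                                core = c(2L, 13L), core_mult = 2,
                                max_bulges = 2L, protect = c(10L, 11L)) {
  list(mismatch = mismatch, gu = gu, bulge = bulge, core = as.integer(core),
       core_mult = core_mult, max_bulges = as.integer(max_bulges),
       protect = as.integer(protect))
}

check_alphabet <- function(x) {
  if (any(grepl("[^ACGT]", x)))
    stop("sequence contains characters outside the A/C/G/T(U) alphabet")
  x
}

#' Score the antisense pairing of an sRNA against a target window
#'
#' Minimum-penalty antiparallel alignment of the sRNA (5'->3') against the
#' window (target sense, 5'->3'; sRNA position 1 pairs the 3'-most window
#' base), consuming the whole window. The predicted cleavage site is the
#' window position paired to sRNA position 10 (the 5' end of the downstream
#' cleavage fragment).
#'
#' @param srna small RNA sequence (RNA or DNA).
#' @param target_window target site sequence; length must be within the
#'   sRNA length +/- `max_bulges`.
#' @param params [target_score_params()].
#' @return list of class `target_alignment`: `score`, `site_start`,
#'   `site_end` (window coordinates), `cleavage_pos`, `pairing` (one char
#'   per sRNA position: `|` Watson-Crick, `o` G:U, `.` mismatch, `-`
#'   bulged sRNA base).
#' @export
score_pairing <- function(srna, target_window, params = target_score_params()) {
  srna <- check_alphabet(rna_to_dna(srna))
  target_window <- check_alphabet(rna_to_dna(target_window))
  if (abs(nchar(target_window) - nchar(srna)) > params$max_bulges)
    stop("window length outside sRNA length +/- max_bulges")
  r <- score_window_cpp(srna, target_window, params$mismatch, params$gu,
                        params$bulge, params$core[1], params$core[2],
                        params$core_mult, params$max_bulges,
                        params$protect[1], params$protect[2])
  if (!is.finite(r$score)) stop("no admissible alignment for this window")
  r$srna <- srna
  class(r) <- "target_alignment"
  r
}

#' @export
print.target_alignment <- function(x, ...) {
  cat(sprintf("target_alignment: score %.2f, site %d-%d, cleavage %s\n",
              x$score, x$site_start %||% NA, x$site_end %||% NA,
              x$cleavage_pos %||% NA))
  cat(" sRNA 5'-", x$srna, "-3'\n        ", x$pairing, "\n", sep = "")
  invisible(x)
}

#' Predict targets of an sRNA across a transcriptome
#'
#' Scans every transcript for minimum-penalty antisense windows and returns
#' alignments with score at or below the cutoff, sorted by ascending score.
#' The cutoff is inclusive: sites scoring exactly the threshold are
#' reported (the published tubulin targets sit exactly at 4.0).
#' Overlapping window variants sharing a cleavage position are collapsed to
#' the best-scoring one.
#'
#' @param srna small RNA sequence.
#' @param transcriptome named character vector of transcript sequences.
#' @param cutoff maximum penalty score (inclusive).
#' @param params [target_score_params()].
#' @return data.frame: `srna`, `transcript_id`, `site_start`, `site_end`,
#'   `score`, `cleavage_pos`, `pairing` (transcript coordinates, 1-based).
#' @export
predict_targets <- function(srna, transcriptome, cutoff = 4.0,
                            params = target_score_params()) {
  if (!length(transcriptome)) stop("empty transcriptome")
  srna_dna <- check_alphabet(rna_to_dna(srna))
  out <- lapply(names(transcriptome), function(tx) {
    d <- target_scan_cpp(srna_dna, toupper(transcriptome[[tx]]),
                         params$mismatch, params$gu, params$bulge,
                         params$core[1], params$core[2], params$core_mult,
                         params$max_bulges, params$protect[1],
                         params$protect[2], cutoff)
    if (!nrow(d)) return(NULL)
    # collapse alignment variants that predict the same cleavage position
    d <- d[order(d$score, d$site_start), , drop = FALSE]
    d <- d[!duplicated(d$cleavage_pos), , drop = FALSE]
    d$transcript_id <- tx
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(srna = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      score = numeric(), cleavage_pos = integer(),
                      pairing = character()))
  out$srna <- srna_dna
  out <- out[order(out$score, out$transcript_id, out$site_start), ]
  rownames(out) <- NULL
  out[, c("srna", "transcript_id", "site_start", "site_end", "score",
          "cleavage_pos", "pairing")]
}
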