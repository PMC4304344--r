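#' Read a miRBase-style mature miRNA catalog
#'
#' @param path FASTA of mature sequences (RNA or DNA alphabet).
#' @return data.frame with `id` and `sequence` (DNA). Families may share one
#'   sequence; ids must be unique.
#' @export
read_mirna_catalog <- function(path) {
  x <- read_fasta(path)
  mirna_catalog(names(x), x)
}

#' @rdname read_mirna_catalog
#' @param ids,sequences catalog entries given directly.
#' @export
mirna_catalog <- function(ids, sequences) {
  if (anyDuplicated(ids)) stop("duplicate catalog ids")
  data.frame(id = ids, sequence = unname(rna_to_dna(sequences)),
             stringsAsFactors = FALSE)
}

#' Quantify known miRNAs by perfect sequence identity
#'
#' A miRNA's abundance is the normalized abundance of the distinct sequence
#' exactly equal to its mature sequence (0 when absent). Family members with
#' identical mature sequences all report the same abundance; library totals
#' are computed from sequences, so families never double-count.
#'
#' @param mat abundance matrix from [abundance_matrix()] (rows: sequences).
#' @param catalog data.frame from [mirna_catalog()].
#' @return numeric matrix (rows: catalog ids, columns: libraries), carrying
#'   the input's `library_info` attribute.
#' @export
quantify_mirnas <- function(mat, catalog) {
  if (anyDuplicated(catalog$id)) stop("duplicate catalog ids")
  idx <- match(catalog$sequence, rownames(mat))
  out <- matrix(0, nrow = nrow(catalog), ncol = ncol(mat),
                dimnames = list(catalog$id, colnames(mat)))
  found <- !is.na(idx)
  out[found, ] <- mat[idx[found], , drop = FALSE]
  attr(out, "library_info") <- attr(mat, "library_info")
  out
}

stage_column <- function(library_info, tissue, stage) {
  i <- which(library_info$tissue == tissue & library_info$stage == stage)
  if (length(i) != 1)
    stop("need exactly one ", tissue, "/", stage, " library")
  library_info$library_id[i]
}

#' Screen for senescence-regulated miRNAs
#'
#' For each miRNA exceeding the abundance floor in at least one library of
#' the tissue, computes the fold change of each senescence stage against
#' the mature stage, FC = (a_stage + c) / (a_mature + c), and flags
#' candidates whose early or late senescence fold change reaches `fold`
#' (up) or `1/fold` (down).
#'
#' @param mat miRNA abundance matrix (TP2M) with a `library_info` attribute.
#' @param tissue tissue whose four stages are screened.
#' @param floor abundance floor (TP2M) that must be exceeded in >= 1 library
#'   of the tissue.
#' @param fold fold-change threshold.
#' @param pseudocount c added to both numerator and denominator (guards
#'   zero denominators; in TP2M units).
#' @param library_info optional design data.frame overriding the attribute.
#' @return data.frame with per-stage abundance, fold changes, `passed_floor`
#'   and `candidate_up`/`candidate_down` flags.
#' @export
screen_differential <- function(mat, tissue, floor = 50, fold = 3,
                                pseudocount = 1, library_info = NULL) {
  info <- library_info %||% attr(mat, "library_info")
  stopifnot(!is.null(info))
  cols <- vapply(senescence_stages(), function(st)
    stage_column(info, tissue, st), character(1))
  a <- mat[, cols, drop = FALSE]
  colnames(a) <- senescence_stages()
  passed <- apply(a > floor, 1, any)
  fc <- (a + pseudocount) / (a[, "mature"] + pseudocount)
  up <- passed & (fc[, "early_senescence"] >= fold |
                    fc[, "late_senescence"] >= fold)
  down <- passed & (fc[, "early_senescence"] <= 1 / fold |
                      fc[, "late_senescence"] <= 1 / fold)
  data.frame(mirna = rownames(mat), tissue = tissue,
             young = a[, "young"], mature = a[, "mature"],
             early_senescence = a[, "early_senescence"],
             late_senescence = a[, "late_senescence"],
             fc_young = fc[, "young"],
             fc_early = fc[, "early_senescence"],
             fc_late = fc[, "late_senescence"],
             passed_floor = passed, candidate_up = up, candidate_down = down,
             unchanged = passed & !up & !down,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise miRNA expression correlation between libraries
#'
#' R-squared of the least-squares fit over miRNAs exceeding the floor in
#' either library, computed on log10(TP2M + 1) by default (linear scale
#' retained as an option).
#'
#' @param mat miRNA abundance matrix.
#' @param lib_a,lib_b library ids (columns).
#' @param floor abundance floor applied as "either library exceeds".
#' @param log compute on log10(x + 1) scale.
#' @return R-squared, with the number of miRNAs used as attribute `n`.
#' @export
correlate_libraries <- function(mat, lib_a, lib_b, floor = 50, log = TRUE) {
  a <- mat[, lib_a]
  b <- mat[, lib_b]
  keep <- a > floor | b > floor
  if (sum(keep) < 3) stop("fewer than 3 shared miRNAs above the floor")
  x <- a[keep]; y <- b[keep]
  if (log) { x <- log10(x + 1); y <- log10(y + 1) }
  r2 <- stats::cor(x, y)^2
  attr(r2, "n") <- sum(keep)
  r2
}
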