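#' Reverse complement of DNA character vectors
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between RNA and DNA alphabets
#'
#' Sequence catalogs (miRBase-style) print mature sequences in RNA; all
#' internal computation uses the DNA alphabet.
#'
#' @param x character vector.
#' @return character vector in the other alphabet, uppercased.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-library sub-seed; kept well below 2^31.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(index)
}

random_dna <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table syntax (.N, :=) is used from this package's namespace
.datatable.aware <- TRUE
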