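# Independent brute-force oracles used across tests. These deliberately use
# plain recursive enumeration / naive scans, not the package's DP or index.

can_pair_chr <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
}

# exhaustive maximum base-pairing over nested structures
enum_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (can_pair_chr(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(ch))
}

# exhaustive best single-stem score: value = pairs - lambda * unpaired inside
# the stem, hairpin loop free; score = 2 * value / span, max over spans
enum_stem_score <- function(seq, min_loop = 3L, lambda = 1.25, min_span = 4L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- 0
    if (j - i > min_loop && can_pair_chr(ch[i], ch[j]))
      best <- max(best, rec(i + 1L, j - 1L) + 1)
    best <- max(best, rec(i + 1L, j) - lambda, rec(i, j - 1L) - lambda)
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i + 1L < min_span) next
    best <- max(best, 2 * rec(i, j) / (j - i + 1L))
  }
  best
}

# exhaustive minimum-penalty antisense alignment (mirrors the move set of the
# scoring scheme: pair/mismatch, sRNA bulge, target bulge) over all anchors
enum_target_min <- function(srna, tx, params = target_score_params()) {
  s <- strsplit(srna, "")[[1]]
  t <- strsplit(tx, "")[[1]]
  m <- length(s); n <- length(t)
  w <- function(i) if (i >= params$core[1] && i <= params$core[2])
    params$core_mult else 1
  pen <- function(i, j) {
    a <- s[i]; b <- t[j]
    cls <- if (can_pair_chr(a, b)) {
      if ((a == "G" && b == "T") || (a == "T" && b == "G")) "gu" else "wc"
    } else "mm"
    switch(cls, wc = 0, gu = params$gu * w(i), mm = params$mismatch * w(i))
  }
  rec <- function(i, j, b) {
    if (i > m) return(0)
    best <- Inf
    prot <- i >= params$protect[1] && i <= params$protect[2]
    if (j >= 1) best <- min(best, pen(i, j) + rec(i + 1L, j - 1L, b))
    if (b < params$max_bulges && !prot) {
      best <- min(best, params$bulge * w(i) + rec(i + 1L, j, b + 1L))
      if (j >= 1)
        best <- min(best, params$bulge * w(i) + rec(i, j - 1L, b + 1L))
    }
    best
  }
  best <- Inf
  for (j1 in seq.int(max(1L, m - params$max_bulges), n))
    best <- min(best, rec(1L, j1, 0L))
  best
}

# naive exact-occurrence scan on both strands (0-based half-open)
naive_scan <- function(seqs, genome) {
  out <- list()
  for (q in unique(seqs)) {
    for (ch in names(genome)) {
      for (std in c("+", "-")) {
        pat <- if (std == "+") q else senescmir::revcomp(q)
        at <- gregexpr(pat, genome[[ch]], fixed = TRUE)[[1]]
        at <- at[at > 0]
        if (length(at))
          out[[length(out) + 1L]] <- data.frame(
            sequence = q, chrom = ch, start = at - 1L,
            end = at - 1L + nchar(q), strand = std, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  out <- do.call(rbind, out)
  out <- out[order(out$sequence, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
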