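adapter <- "CTGTAGGCACCATCAAT"

test_that("adapter trimming returns the insert or a classified rejection", {
  sen3 <- "TGCAAGGTTCAAGAACGGATC"
  tr <- trim_adapter(c(
    paste0(sen3, adapter),                 # clean 21-nt insert
    paste0(strrep("A", 25), "GGGGGGG"),    # no adapter anywhere
    adapter,                               # adapter only: empty insert
    paste0("ACGTN", strrep("ACGT", 5), adapter),  # N in insert
    paste0(strrep("AC", 16), adapter)),    # 32 nt: too long
    adapter)
  expect_identical(tr$insert[1], sen3)
  expect_identical(nchar(tr$insert[1]), 21L)
  expect_identical(tr$reason, c("ok", "no_adapter", "too_short",
                                "non_acgt", "too_long"))
  expect_identical(sum(tr$kept) + sum(!tr$kept), nrow(tr))
})

test_that("exact mapper agrees with a naive scan on random queries", {
  set.seed(101)
  genome <- c(chrA = random_seq(30000), chrB = random_seq(20000))
  # mix of genuine substrings (both strands) and random queries
  qs <- c(
    vapply(1:60, function(i) {
      ch <- sample(names(genome), 1)
      L <- sample(18:28, 1)
      st <- sample(nchar(genome[[ch]]) - L, 1)
      s <- substr(genome[[ch]], st, st + L - 1)
      if (runif(1) < 0.5) revcomp(s) else s
    }, character(1)),
    vapply(1:60, function(i) random_seq(sample(18:28, 1)), character(1)))
  idx <- genome_index(genome)
  got <- map_exact(qs, index = idx)
  expect_identical(got, naive_scan(qs, genome))
})

test_that("short queries and palindromes map on both strands correctly", {
  pal <- paste0("ACGTACGTA", revcomp("ACGTACGTA"))  # 18-nt palindrome
  g <- c(chr1 = paste0(strrep("A", 30), pal, strrep("C", 30)))
  h <- map_exact(pal, g)
  expect_identical(nrow(h), 2L)
  expect_setequal(h$strand, c("+", "-"))
  expect_true(all(h$start == 30L))
  # 15-nt query goes through the short-query scan
  q15 <- substr(pal, 1, 15)
  h15 <- map_exact(q15, g)
  expect_identical(h15, naive_scan(q15, g))
  expect_identical(nrow(map_exact("TGCATGCATGCATGCATG", g)), 0L)
})

test_that("structural filtering removes by any-hit overlap and conserves counts", {
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 501), c(200, 600)), strand = "+",
    type = c("rRNA", "gene"))
  rs <- read_set(data.frame(sequence = c("AAAAAAAAAAAAAAAAAAAA",
                                         "CCCCCCCCCCCCCCCCCCCC",
                                         "GGGGGGGGGGGGGGGGGGGG"),
                            count = c(5L, 7L, 9L)), "lib")
  hits <- data.frame(
    sequence = c("AAAAAAAAAAAAAAAAAAAA",            # wholly inside rRNA
                 "CCCCCCCCCCCCCCCCCCCC",            # genic hit ...
                 "CCCCCCCCCCCCCCCCCCCC",            # ... and a 1-nt rRNA touch
                 "GGGGGGGGGGGGGGGGGGGG"),           # genic only
    chrom = "chr1", start = c(120L, 520L, 181L, 520L),
    end = c(140L, 540L, 201L, 540L), strand = "+",
    stringsAsFactors = FALSE)
  fs <- filter_structural(rs, hits, ann)
  expect_identical(fs$retained$records$sequence, "GGGGGGGGGGGGGGGGGGGG")
  expect_identical(fs$structural_count, 12L)
  expect_identical(sum(fs$retained$records$count) + fs$structural_count,
                   sum(rs$records$count))
  # no structural annotations: identity
  fs2 <- filter_structural(rs, hits, ann[ann$type == "gene"])
  expect_identical(fs2$retained$records, rs$records)
  # unknown feature types warn and are ignored
  ann$type[2] <- "lncRNA_guess"
  expect_warning(filter_structural(rs, hits, ann), "unknown")
})

test_that("TP2M normalization is exact, scale-invariant and sums to scale", {
  rs <- read_set(data.frame(sequence = c(strrep("A", 20), strrep("C", 20)),
                            count = c(5L, 5L)), "lib")
  n <- normalize_abundance(rs, 2e6)
  expect_identical(n$tp, c(1e6, 1e6))
  rs2 <- read_set(data.frame(sequence = rs$records$sequence,
                             count = rs$records$count * 7L), "lib")
  expect_equal(normalize_abundance(rs2, 2e6)$tp, n$tp)
  set.seed(3)
  rs3 <- collapse_reads(sample(vapply(1:50, function(i) random_seq(20),
                                      character(1)), 500, TRUE))
  expect_equal(sum(normalize_abundance(rs3, 2e6)$tp), 2e6)
  expect_equal(max(normalize_abundance(rs3, 1e7)$tp) /
                 max(normalize_abundance(rs3, 2e6)$tp), 5)
  expect_error(normalize_abundance(read_set(
    data.frame(sequence = character(), count = integer()))), "empty")
})

test_that("library stats report distinct counts matching a set oracle", {
  set.seed(9)
  pool <- vapply(1:200, function(i) random_seq(sample(20:24, 1)), character(1))
  draws <- sample(pool, 3000, TRUE)
  rs <- collapse_reads(draws, "x", "leaf", "mature")
  st <- library_stats(3000L, 3000L, 0L, rs)
  expect_identical(st$distinct, length(unique(draws)))
  hist <- attr(st, "size_histogram")
  expect_equal(sum(hist), 2e6)
  # single-sequence library: all mass at its length
  one <- collapse_reads(rep(strrep("A", 21), 100), "y")
  h1 <- attr(library_stats(100L, 100L, 0L, one), "size_histogram")
  expect_identical(names(h1), "21")
})

test_that("per-stage read accounting is conserved through processing", {
  ref <- small_ref()
  sim <- simulate_srna_library(ref, "leaf", "mature")
  idx <- genome_index(ref$genome)
  pr <- process_srna_library(sim$reads, idx, ref$annotations,
                             ref$config$adapter3, "LM", "leaf", "mature")
  a <- pr$accounting
  expect_identical(a[["raw"]], a[["trimmed_kept"]] + a[["trimmed_rejected"]])
  expect_identical(a[["genome_matched"]],
                   a[["structural"]] + a[["retained"]])
  expect_identical(a[["trimmed_kept"]],
                   a[["genome_matched"]] + a[["unmatched"]])
  # simulated reads are all genomic, so nothing legitimate is lost
  expect_identical(a[["unmatched"]], 0L)
})
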