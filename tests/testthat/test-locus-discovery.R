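test_that("candidate filter keeps induced unknowns and drops known/flat", {
  seqs <- c("AAAAAAAAAAAAAAAAAAAAA",   # induced, unknown: candidate
            "CCCCCCCCCCCCCCCCCCCCC",   # induced tenfold but in catalog
            "GGGGGGGGGGGGGGGGGGGGG")   # flat background
  m <- design_matrix(c(10, 60, 700, 900,
                       10, 80, 800, 800,
                       400, 400, 410, 420), seqs)
  cat <- mirna_catalog("known-mir", seqs[2])
  expect_identical(candidate_sequences(m, cat), seqs[1])
})

test_that("clustering merges nearby hits and applies the strand-bias rule", {
  hit <- function(seq, start, strand)
    data.frame(sequence = seq, chrom = "chr1", start = start,
               end = start + nchar(seq), strand = strand,
               stringsAsFactors = FALSE)
  s1 <- strrep("A", 21); s2 <- strrep("C", 21); s3 <- strrep("G", 21)
  # two candidates 10 nt apart -> one window; an antisense passenger adds
  # minus mass
  hits <- rbind(hit(s1, 1000, "+"), hit(s2, 1031, "+"), hit(s3, 1010, "-"))
  w95 <- cluster_and_bias(c(s1, s2), hits,
                          mass = stats::setNames(c(47.5, 47.5, 10),
                                                 c(s1, s2, s3)))
  expect_identical(nrow(w95), 1L)
  expect_equal(w95$strand_bias, 95 / 105)
  expect_true(w95$kept)   # 0.905 > 0.9
  w60 <- cluster_and_bias(c(s1, s2), hits,
                          mass = stats::setNames(c(30, 30, 40), c(s1, s2, s3)))
  expect_equal(w60$strand_bias, 0.6)
  expect_false(w60$kept)
  # candidates without hits are skipped with a message
  expect_message(cluster_and_bias(c(s1, "TTTTTTTTTTTTTTTTTTTTT"),
                                  hits[1, ], stats::setNames(10, s1)),
                 "skipped")
})

test_that("distant candidate clusters stay separate windows", {
  s1 <- strrep("A", 21); s2 <- strrep("C", 21)
  hits <- data.frame(sequence = c(s1, s2), chrom = "chr1",
                     start = c(1000L, 5000L), end = c(1021L, 5021L),
                     strand = "+", stringsAsFactors = FALSE)
  w <- cluster_and_bias(c(s1, s2), hits,
                        mass = stats::setNames(c(10, 10), c(s1, s2)))
  expect_identical(nrow(w), 2L)
})

test_that("Nussinov pair counts equal exhaustive enumeration on short RNAs", {
  set.seed(13)
  cases <- c(vapply(1:18, function(i) random_seq(sample(8:16, 1)),
                    character(1)),
             "GGGAAACCC", "GCGCAAAGCGC", "AAAAAAAAAAAA")
  for (s in cases)
    expect_identical(nussinov_pairs(s), enum_max_pairs(s), info = s)
  # the minimum-loop constraint is honored
  expect_identical(nussinov_pairs("GAAC"), 0L)  # loop of 2 < 3
  expect_identical(nussinov_pairs("GAAAC"), 1L)
})

test_that("stem-loop score equals exhaustive single-stem enumeration", {
  set.seed(14)
  for (i in 1:12) {
    s <- random_seq(sample(8:14, 1))
    got <- stem_fold_cpp(s, 3L, 1.25, 4L)
    expect_equal(got$score, enum_stem_score(s, 3L, 1.25, 4L), info = s)
  }
})

test_that("hairpin scoring separates inverted repeats from random sequence", {
  set.seed(15)
  S <- random_seq(60)
  ir <- paste0(S, "GAAATCAA", revcomp(S))
  rep_ir <- fold_hairpin(ir)
  expect_gt(rep_ir$score, 0.9)
  expect_true(rep_ir$passes)
  # the fixture precursor passes, a shuffled version of it does not
  prec <- sen_srna_locus()$precursor
  expect_true(fold_hairpin(prec)$passes)
  shuf <- paste(sample(strsplit(prec, "")[[1]]), collapse = "")
  expect_lt(fold_hairpin(shuf)$score, fold_hairpin(prec)$score)
  expect_error(fold_hairpin(random_seq(30)), "50")
})

test_that("hairpin score is invariant under sequence reversal", {
  set.seed(16)
  for (i in 1:8) {
    s <- random_seq(80)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(fold_hairpin(s)$score, fold_hairpin(r)$score)
  }
})

test_that("locus report computes precision and abundant-sRNA floors", {
  win <- list(chrom = "chr1", start = 900L, end = 1100L)
  one <- "ACGTACGTACGTACGTACGTA"
  mat1 <- matrix(1000, 1, 1, dimnames = list(one, "L1"))
  hits1 <- data.frame(sequence = one, chrom = "chr1", start = 1000L,
                      end = 1021L, strand = "+", stringsAsFactors = FALSE)
  r1 <- report_locus(win, mat1, hits1, abundance_floor = 0)
  expect_equal(r1$precision, 1)
  expect_true(r1$passes_meyers)
  expect_identical(nrow(r1$srnas), 1L)
  # 50 ragged-end sequences with uniform mass: precision 2/50, fails
  set.seed(17)
  seqs <- vapply(1:50, function(i) random_seq(21), character(1))
  starts <- 900L + 3L * (0:49)
  mat50 <- matrix(100, 50, 1, dimnames = list(seqs, "L1"))
  hits50 <- data.frame(sequence = seqs, chrom = "chr1", start = starts,
                       end = starts + 21L, strand = "+",
                       stringsAsFactors = FALSE)
  r50 <- report_locus(list(chrom = "chr1", start = 880L, end = 1120L),
                      mat50, hits50, abundance_floor = 0)
  expect_equal(r50$precision, 0.04)
  expect_false(r50$passes_meyers)
  # abundance floor: only sequences at or above it are reported
  r50f <- report_locus(list(chrom = "chr1", start = 880L, end = 1120L),
                       mat50, hits50, abundance_floor = 100 * 1e7 / 2e6 + 1)
  expect_identical(nrow(r50f$srnas), 0L)
  # track covers the window and carries all the mass
  expect_identical(nrow(r1$track), win$end - win$start)
  expect_equal(sum(r1$track$abundance > 0), 21L)
})

test_that("coterminal variants within 1 nt group as one excision product", {
  a <- "ACGTACGTACGTACGTACGTA"
  b <- "CGTACGTACGTACGTACGTAC"   # same locus shifted by 1
  c3 <- "GGGGGTTTTTCCCCCAAAAAG"  # far away in the window
  mat <- matrix(c(600, 300, 100), 3, 1,
                dimnames = list(c(a, b, c3), "L1"))
  hits <- data.frame(sequence = c(a, b, c3), chrom = "chr1",
                     start = c(1000L, 1001L, 1050L),
                     end = c(1021L, 1022L, 1071L), strand = "+",
                     stringsAsFactors = FALSE)
  r <- report_locus(list(chrom = "chr1", start = 950L, end = 1120L),
                    mat, hits, abundance_floor = 0)
  # a+b group together; top two clusters = (a+b) and c3 -> precision 1
  expect_equal(r$precision, 1)
})
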