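make_tx <- function() {
  set.seed(51)
  shared <- random_seq(20)
  list(tx = c(T1 = paste0(random_seq(100), shared, random_seq(200)),
              T2 = paste0(random_seq(50), shared, random_seq(80))),
       shared = shared)
}

test_that("PARE profiles place tag 5' ends and conserve mass", {
  x <- make_tx()
  tagA <- substr(x$tx[["T1"]], 31, 50)
  reads <- c(rep(tagA, 7), rep(x$shared, 3), rep(substr(random_seq(40), 1, 20), 2))
  pp <- build_pare_profiles(reads, x$tx, "P1", "mature")
  prof <- pp$profiles
  expect_equal(prof$count[prof$transcript_id == "T1" & prof$pos == 31], 7)
  # a multi-transcript tag increments each transcript
  expect_equal(prof$count[prof$transcript_id == "T1" & prof$pos == 101], 3)
  expect_equal(prof$count[prof$transcript_id == "T2" & prof$pos == 51], 3)
  # per-transcript mass equals that transcript's mapped tags
  expect_equal(sum(prof$count[prof$transcript_id == "T1"]), 10)
  expect_equal(sum(prof$count), pp$mapped_total)
  # distinct matches a set-based oracle; normalization sums to scale
  expect_identical(pp$stats$distinct, length(unique(c(tagA, x$shared))))
  expect_equal(sum(prof$norm), 1e7)
})

test_that("cleavage validation implements the position-10 window rule", {
  x <- make_tx()
  site <- 120L
  tag <- substr(x$tx[["T1"]], site, site + 19)
  noise <- vapply(1:50, function(i) {
    p <- sample(setdiff(1:250, site), 1)
    substr(x$tx[["T1"]], p, p + 19)
  }, character(1))
  pp <- build_pare_profiles(c(rep(tag, 40), noise), x$tx)
  aln <- list(transcript_id = "T1", cleavage_pos = site)
  ev <- validate_cleavage(aln, pp)
  expect_true(ev$supported)
  expect_identical(ev$site_rank, 1L)
  expect_gt(ev$fraction, 0.3)
  # zero reads at the site: unsupported
  ev0 <- validate_cleavage(list(transcript_id = "T2", cleavage_pos = 10L), pp)
  expect_false(ev0$supported)
  # shifting the signal by +3: unsupported at window 0, supported at 3
  aln3 <- list(transcript_id = "T1", cleavage_pos = site - 3L)
  expect_false(validate_cleavage(aln3, pp, window = 0)$supported)
  expect_true(validate_cleavage(aln3, pp, window = 3)$supported)
})

test_that("the verdict is invariant to library depth scaling", {
  x <- make_tx()
  site <- 80L
  tag <- substr(x$tx[["T1"]], site, site + 19)
  other <- substr(x$tx[["T1"]], 140, 159)
  mk <- function(k) build_pare_profiles(c(rep(tag, 5 * k), rep(other, 9 * k)),
                                        x$tx)
  aln <- list(transcript_id = "T1", cleavage_pos = site)
  e1 <- validate_cleavage(aln, mk(1))
  e2 <- validate_cleavage(aln, mk(20))
  expect_identical(e1$supported, e2$supported)
  expect_identical(e1$site_rank, e2$site_rank)
  expect_equal(e1$fraction, e2$fraction)
})

test_that("false support on uniform null libraries stays near chance", {
  set.seed(52)
  tx <- c(N1 = random_seq(1000))
  npos <- 1000 - 19
  site <- 400L
  p0 <- 5 / npos   # chance that a fixed site ranks in the top 5
  hits <- 0L
  n_seeds <- 100
  for (i in seq_len(n_seeds)) {
    pos <- sample(npos, 1e4, replace = TRUE)
    reads <- substring(tx[["N1"]], pos, pos + 19)
    pp <- build_pare_profiles(reads, tx)
    ev <- validate_cleavage(list(transcript_id = "N1", cleavage_pos = site),
                            pp, rank_max = 5)
    hits <- hits + ev$supported
  }
  # observed false-support count within the upper binomial tail of chance
  expect_lte(hits, qbinom(0.999, n_seeds, p0) + 1)
})

test_that("stage tracking labels trends in agreement with rank correlation", {
  x <- make_tx()
  site <- 150L
  tag <- substr(x$tx[["T1"]], site, site + 19)
  filler <- substr(x$tx[["T2"]], 10, 29)
  stages <- senescence_stages()
  ramp <- c(2, 5, 40, 90)
  profs <- lapply(seq_along(stages), function(i)
    build_pare_profiles(c(rep(tag, ramp[i]), rep(filler, 100)),
                        x$tx, paste0("P", i), stages[i]))
  names(profs) <- paste0("P", 1:4)
  aln <- data.frame(transcript_id = "T1", cleavage_pos = site)
  tr <- track_site_across_stages(aln, profs)
  expect_identical(tr$trends$trend, "increasing")
  # oracle: direct Spearman on the tabulated abundances
  rho <- cor(match(tr$table$stage, stages), tr$table$abundance,
             method = "spearman")
  expect_equal(tr$trends$rho, rho)
  # flat signal: no trend
  profs_flat <- lapply(seq_along(stages), function(i)
    build_pare_profiles(c(rep(tag, 50), rep(filler, 100)),
                        x$tx, paste0("F", i), stages[i]))
  names(profs_flat) <- paste0("F", 1:4)
  trf <- track_site_across_stages(aln, profs_flat)
  expect_identical(trf$trends$trend, "none")
  expect_error(track_site_across_stages(aln, profs[1]), "2 stages")
})
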