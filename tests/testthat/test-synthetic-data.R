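test_that("reference build embeds precursors at recorded positions", {
  ref <- small_ref()
  mat <- ref$ledger$matures
  expect_gt(nrow(mat), 0)
  for (r in seq_len(nrow(mat))) {
    got <- substr(ref$genome[[mat$chrom[r]]], mat$start[r] + 1L,
                  mat$start[r] + mat$size[r])
    expect_identical(got, mat$sequence[r])
  }
  # the five fixture matures are all present with their published sizes
  sen <- mat[mat$locus == "sen-sRNA", ]
  expect_identical(sort(sen$size), sort(c(21L, 21L, 21L, 24L, 21L)))
})

test_that("structural annotation intervals are disjoint from planted loci", {
  ref <- small_ref()
  ann <- ref$annotations
  struct <- ann[ann$type %in% c("tRNA", "rRNA", "snoRNA", "snRNA")]
  loci <- ann[ann$type == "gene"]
  expect_length(GenomicRanges::findOverlaps(struct, loci,
                                            ignore.strand = TRUE), 0)
  expect_gt(length(struct), 0)
})

test_that("zero-locus config gives a pure random genome and empty ledger", {
  cfg <- simulation_config(seed = 7L, chrom_length = 20000L,
                           srna_depth = 1000, tissues = "leaf",
                           planted_loci = list())
  ref <- build_reference(cfg)
  expect_identical(nrow(ref$ledger$matures), 0L)
  expect_identical(nrow(ref$ledger$expression), 0L)
  expect_false(any(ref$annotations$type == "gene"))
})

test_that("same seed reproduces byte-identical reference and library files", {
  cfg <- simulation_config(seed = 11L, chrom_length = 20000L,
                           srna_depth = 2000, pare_depth = 1000,
                           tissues = "leaf")
  d1 <- file.path(tempdir(), "ref_a")
  d2 <- file.path(tempdir(), "ref_b")
  write_reference(build_reference(cfg), d1)
  write_reference(build_reference(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulated sRNA libraries conserve depth and carry the adapter", {
  ref <- small_ref()
  sim <- simulate_srna_library(ref, "leaf", "late_senescence")
  expect_length(sim$reads, ref$config$srna_libraries$depth[1])
  expect_true(all(nchar(sim$reads) == ref$config$raw_read_length))
  cc <- attr(sim$reads, "component_counts")
  expect_identical(sum(cc), length(sim$reads))
  # trimming recovers nearly all inserts (a few contain the adapter prefix
  # by chance and trim early)
  tr <- trim_adapter(sim$reads, ref$config$adapter3)
  expect_gt(mean(tr$kept), 0.99)
})

test_that("structural read counts follow the configured binomial fraction", {
  cfg <- simulation_config(seed = 5L, chrom_length = 20000L,
                           srna_depth = 10000, tissues = "leaf",
                           planted_loci = list(), structural_fraction = 0.3,
                           background_fraction = 0.1)
  ref <- build_reference(cfg)
  sim <- simulate_srna_library(ref, "leaf", "mature")
  n <- attr(sim$reads, "component_counts")[["structural"]]
  sigma <- sqrt(10000 * 0.3 * 0.7)
  expect_lt(abs(n - 3000), 3 * sigma)
})

test_that("a zero-weight stage yields no planted reads, a ramped one does", {
  mat21 <- with_seed(33L, random_seq(21))
  loc <- planted_locus("rampA", c(rampA = mat21),
                       stage_multiplier = c(young = 0, mature = 0,
                                            early_senescence = 0,
                                            late_senescence = 1),
                       base_fraction = 0.02)
  cfg <- simulation_config(seed = 6L, chrom_length = 20000L,
                           srna_depth = 5000, tissues = "leaf",
                           planted_loci = list(loc))
  ref <- build_reference(cfg)
  rd_m <- simulate_srna_library(ref, "leaf", "mature")$reads
  rd_l <- simulate_srna_library(ref, "leaf", "late_senescence")$reads
  expect_identical(sum(startsWith(rd_m, mat21)), 0L)
  expect_gt(sum(startsWith(rd_l, mat21)), 0L)
  expect_error(simulate_srna_library(ref, "leaf", "bogus"), "unknown")
})

test_that("PARE reads are 20 nt and pure-signal libraries hit the ledger site", {
  mat21 <- with_seed(44L, random_seq(21))
  loc <- planted_locus(
    "pareA", c(pareA = mat21), base_fraction = 0.01,
    stage_multiplier = c(young = 1, mature = 1, early_senescence = 1,
                         late_senescence = 1),
    targets = list(target_spec("TGT1", "pareA",
                               pare_fraction = c(young = 0, mature = 1,
                                                 early_senescence = 0.5,
                                                 late_senescence = 0.5))))
  cfg <- simulation_config(seed = 8L, chrom_length = 20000L,
                           srna_depth = 1000, pare_depth = 2000,
                           tissues = "leaf", planted_loci = list(loc))
  ref <- build_reference(cfg)
  sim <- simulate_pare_library(ref, "mature")  # tag fraction 1: no off-target
  expect_true(all(nchar(sim$reads) == 20))
  cl <- ref$ledger$targets$cleavage_pos[1]
  tag <- substr(ref$transcriptome[["TGT1"]], cl, cl + 19)
  expect_true(all(sim$reads == tag))
  # all-off-target stage: no enrichment at the site beyond uniform
  sim0 <- simulate_pare_library(ref, "young")
  hit <- sum(sim0$reads == tag)
  npos <- sum(pmax(nchar(ref$transcriptome) - 19, 0))
  expect_lt(hit, 5 + 3 * 2000 / npos * 20)
})

test_that("over-subscribed signal fractions are rejected at config time", {
  greedy <- planted_locus("greedy", c(g = with_seed(9L, random_seq(21))),
                          base_fraction = 0.9)
  expect_error(simulation_config(planted_loci = list(greedy),
                                 structural_fraction = 0.15),
               "background")
})

test_that("planted matures must be substrings of an explicit precursor", {
  expect_error(planted_locus("bad", c(a = "ACGTACGTACGTACGTACGTA",
                                      b = "TTTTTTTTTTTTTTTTTTTTT"),
                             precursor = "ACGTACGTACGTACGTACGTAGGG"),
               "substring")
  expect_error(planted_locus("multi", c(a = "ACGTACGTACGTACGTACGTA",
                                        b = "CCCCACGTACGTACGTACGTA")),
               "precursor")
})
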