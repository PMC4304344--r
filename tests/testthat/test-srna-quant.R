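test_that("miRNA quantification is strictly perfect-match", {
  seqs <- c("TGCAAGGTTCAAGAACGGATC", "TGCAAGGTTCAAGAACGGATA",
            "AAAACCCCGGGGTTTTAAACC")
  m <- design_matrix(c(500, 500, 500, 500,
                       80, 80, 80, 80,
                       10, 10, 10, 10), seqs)
  cat <- mirna_catalog(c("miR-x", "miR-x-like", "miR-absent"),
                       c(seqs[1], seqs[1], "TTTTTTTTTTTTTTTTTTTTT"))
  q <- quantify_mirnas(m, cat)
  expect_equal(unname(q["miR-x", ]), rep(500, 4))
  # family members with one sequence report the same abundance
  expect_equal(q["miR-x", ], q["miR-x-like", ])
  # 1-nt variant contributes nothing; absent sequence is zero
  expect_equal(unname(q["miR-absent", ]), rep(0, 4))
  expect_true(all(q <= 2e6))
  expect_error(quantify_mirnas(m, rbind(cat, cat[1, ])), "duplicate")
  expect_error(mirna_catalog(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
})

test_that("differential screen applies fold and floor rules", {
  seqs <- c("AAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCC",
            "GGGGGGGGGGGGGGGGGGGGG", "TTTTTTTTTTTTTTTTTTTTT",
            "ACACACACACACACACACACA")
  m <- design_matrix(c(100, 100, 350, 100,    # 3.5x early: up
                       100, 100, 299, 100,    # 2.99x: unchanged (boundary)
                       100, 100, 300, 100,    # exactly 3.0: up (inclusive)
                       120, 120, 30, 40,      # 0.25x: down
                       20, 20, 45, 20),       # never above floor
                     seqs)
  cat <- mirna_catalog(paste0("m", 1:5), seqs)
  sc <- screen_differential(quantify_mirnas(m, cat), "leaf",
                            floor = 50, fold = 3, pseudocount = 0)
  expect_equal(sc$fc_early, c(3.5, 2.99, 3.0, 0.25, 2.25))
  expect_identical(sc$candidate_up, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(sc$candidate_down, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(sc$passed_floor, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(sc$unchanged[2], TRUE)
})

test_that("screen is antisymmetric under swapping mature and test stages", {
  set.seed(21)
  seqs <- vapply(1:30, function(i) random_seq(21), character(1))
  ab <- matrix(10^runif(120, 1.8, 3.5), nrow = 30)
  m1 <- design_matrix(as.vector(t(ab)), seqs)
  # swap the mature and late-senescence columns
  ab2 <- ab[, c(1, 4, 3, 2)]
  m2 <- design_matrix(as.vector(t(ab2)), seqs)
  cat <- mirna_catalog(paste0("m", 1:30), seqs)
  s1 <- screen_differential(quantify_mirnas(m1, cat), "leaf")
  s2 <- screen_differential(quantify_mirnas(m2, cat), "leaf")
  expect_equal(s1$fc_late, 1 / s2$fc_late)
  # a miRNA up purely by its late stage flips to down, and vice versa
  late_only_up <- s1$fc_late >= 3 & s1$fc_early < 3 & 1 / s1$fc_early > 1 / 3
  expect_identical(s2$candidate_down[late_only_up & s1$passed_floor],
                   rep(TRUE, sum(late_only_up & s1$passed_floor)))
})

test_that("library correlation matches closed-form expectation under noise", {
  expect_error(correlate_libraries(design_matrix(rep(1, 8), c(
    "AAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCC")), "LY", "LM"),
    "fewer than 3")
  set.seed(77)
  n <- 2000
  true_log <- rnorm(n, mean = 2.5, sd = 0.7)
  sigma <- 0.3
  a <- 10^(true_log + rnorm(n, 0, sigma))
  b <- 10^(true_log + rnorm(n, 0, sigma))
  seqs <- vapply(seq_len(n), function(i) random_seq(21), character(1))
  m <- design_matrix(rep(0, 4 * n), seqs)
  m[, "LM"] <- a
  m[, "LY"] <- b
  r2 <- correlate_libraries(m, "LM", "LY", floor = 0, log = TRUE)
  r_expected <- (0.7^2 / (0.7^2 + sigma^2))^2
  expect_lt(abs(r2 - r_expected), 0.05)
  # identical columns give exactly 1; a scaled column gives 1 on linear scale
  m[, "LY"] <- m[, "LM"]
  expect_equal(as.numeric(correlate_libraries(m, "LM", "LY", floor = 0)), 1)
  m[, "LY"] <- 2 * m[, "LM"]
  expect_equal(as.numeric(correlate_libraries(m, "LM", "LY", floor = 0,
                                              log = FALSE)), 1)
  expect_gt(as.numeric(correlate_libraries(m, "LM", "LY", floor = 0)), 0.999)
})
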