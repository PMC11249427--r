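cpm_tbl <- function(m) {
  x <- tibble::tibble(mirna = sprintf("f%02d", seq_len(nrow(m))))
  x <- dplyr::bind_cols(x, tibble::as_tibble(
    m, .name_repair = ~ sprintf("s%02d", seq_len(ncol(m)))))
  evmir:::set_count_units(x, "cpm")
}

test_that("the expression filter keeps features at the inclusive boundary", {
  m <- rbind(rep(5, 4), rep(0, 4), c(4.999, 4.999, 4.999, 4.999), rep(5.001, 4))
  keep <- filter_expressed(cpm_tbl(m))
  expect_setequal(keep, c("f01", "f04"))
})

test_that("the group test equals the pooled t closed form and handles degeneracy", {
  x <- matrix(c(1, 2, 3, 11, 12, 13), nrow = 1)
  colnames(x) <- sprintf("s%d", 1:6)
  rownames(x) <- "f"
  g <- rep(c("a", "b"), each = 3)
  p <- unname(group_test(x, g))
  expect_equal(p, oracle_pooled_t_p(c(1, 2, 3), c(11, 12, 13)), tolerance = 1e-12)
  # permuting samples within groups leaves p unchanged
  expect_equal(unname(group_test(x[, c(2, 1, 3, 6, 5, 4), drop = FALSE],
                                 g)), p)
  # identical distributions -> p = 1
  same <- matrix(rep(4, 6), nrow = 1, dimnames = list("f", colnames(x)))
  expect_equal(unname(group_test(same, g)), 1)
  # zero variance, unequal means -> tiny p with warning
  det <- matrix(rep(c(1, 2), each = 3), nrow = 1,
                dimnames = list("f", colnames(x)))
  expect_warning(p0 <- group_test(det, g), "zero within-group variance")
  expect_equal(unname(p0), .Machine$double.xmin)
  expect_error(group_test(x, c("a", "a", "a", "a", "a", "b")), "2 samples")
})

test_that("FDR step-up matches the direct recursion", {
  expect_equal(fdr_step_up(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_step_up(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_step_up(0.037), 0.037)
  set.seed(8)
  p <- runif(200)^2
  adj <- fdr_step_up(p)
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone after sorting
})

test_that("effect statistics follow the signed fold-change convention", {
  expect_equal(round(signed_fold_change(2^-2.03), 2), -4.08)
  expect_equal(round(signed_fold_change(2^0.98), 2), 1.97)
  expect_equal(round(signed_fold_change(2^-0.69), 2), -1.61)
  expect_equal(signed_fold_change(1), 1)
  # sign coherence with log2 ratio on random ratios
  r <- 2^runif(50, -3, 3)
  expect_true(all(sign(signed_fold_change(r)) == sign(log2(r)) |
                    (signed_fold_change(r) == 1 & log2(r) == 0)))

  m <- matrix(c(40, 40, 10, 10), nrow = 1,
              dimnames = list("f", sprintf("s%d", 1:4)))
  es <- effect_stats(cpm_tbl(m), c("Q331K", "Q331K", "WT", "WT"),
                     pseudocount = 0.5)
  expect_equal(es$ratio, 40.5 / 10.5)
  expect_equal(es$log2_ratio, log2(40.5 / 10.5))
  expect_equal(es$fold_change, 40.5 / 10.5)
})

test_that("feature summaries match closed forms", {
  m <- matrix(c(4, 16), nrow = 1, dimnames = list("f", c("s1", "s2")))
  s0 <- summarize_features(cpm_tbl(m), pseudocount = 0)
  expect_equal(s0$geometric_mean, 8)
  expect_equal(s0$arithmetic_mean, 10)
  expect_equal(s0$total_counts, 20)
  expect_equal(s0$maximum_counts, 16)
  # constant vector: total = n*c, max = GM = AM = c
  mc <- matrix(rep(7, 5), nrow = 1,
               dimnames = list("f", sprintf("s%d", 1:5)))
  sc <- summarize_features(cpm_tbl(mc))
  expect_equal(sc$total_counts, 35)
  expect_equal(sc$maximum_counts, 7)
  expect_equal(sc$geometric_mean, 7)
  expect_equal(sc$arithmetic_mean, 7)
  # permutation invariance
  set.seed(1)
  mm <- matrix(rexp(40), nrow = 4,
               dimnames = list(paste0("f", 1:4), sprintf("s%d", 1:10)))
  s1 <- summarize_features(cpm_tbl(mm))
  s2 <- summarize_features(cpm_tbl(mm[, sample(10)]))
  expect_equal(s1, s2)
})

test_that("de_table assembles the full record and select_panel gates it", {
  sim <- planted_simulation(seed = 7, n_features = 200, n_planted = 5)
  de <- de_table(sim$sim$counts, sim$sim$samples)
  expect_s3_class(de, "de_table")
  expect_named(de, c("mirna", "total_counts", "maximum_counts",
                     "geometric_mean", "arithmetic_mean", "p_value",
                     "fdr_step_up", "ratio", "log2_ratio", "fold_change"))
  expect_true(all(diff(de$p_value) >= 0))
  expect_equal(de$log2_ratio, log2(de$ratio), tolerance = 1e-9)
  expect_equal(de$fold_change,
               ifelse(de$ratio >= 1, de$ratio, -1 / de$ratio))
  expect_true(all(de$fdr_step_up >= de$p_value))

  pan <- select_panel(de, compartment = "BDEV")
  expect_true(all(pan$table$p_value < 0.05))
  expect_true(all(abs(pan$table$fold_change) >= 1.5))
  # strict vs inclusive only differ at the boundary
  strict <- select_panel(de, inclusive = FALSE)
  expect_true(all(strict$features %in% pan$features))
  # empty table -> empty panel
  empty <- select_panel(de[0, ])
  expect_length(empty$features, 0)
})

test_that("planted effects are recovered and the null is calibrated", {
  # bias of the log2-ratio estimator over planted features, 5 seeds
  errs <- vapply(1:5, function(s) {
    ps <- planted_simulation(seed = s)
    cpm <- cpm_normalize(ps$sim$counts)
    es <- effect_stats(cpm, ps$sim$samples$genotype)
    idx <- match(ps$planted$mirna, es$mirna)
    mean(es$log2_ratio[idx] - ps$planted$log2fc)
  }, numeric(1))
  expect_true(all(abs(errs) < 0.3))

  # null simulation: pooled p < 0.05 fraction near nominal (3 seeds here;
  # the full 20-seed sweep runs in the acceptance suite)
  fr <- vapply(1:3, function(s) {
    sim <- simulate_counts(synthetic_design(500, 3, dispersion = 0.1, seed = s))
    m <- as.matrix(cpm_normalize(sim$counts)[, -1])
    mean(group_test(log2(m + 0.5), sim$samples$genotype) < 0.05)
  }, numeric(1))
  band <- 2.576 * sqrt(0.05 * 0.95 / (3 * 500))
  expect_lt(abs(mean(fr) - 0.05), band)
})
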