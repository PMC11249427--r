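test_that("discretization follows quantile and merge rules", {
  b <- discretize(1:8, n_bins = 4)
  expect_equal(as.integer(table(b)), c(2, 2, 2, 2))
  expect_equal(length(unique(discretize(rep(3.3, 10)))), 1L)
  # heavy ties merge duplicate cut points into 2 non-empty bins
  b2 <- discretize(c(1, 1, 1, 1, 9), n_bins = 2)
  expect_equal(as.integer(table(b2)), c(4, 1))
  # equal width spans [min, max]
  bw <- discretize(c(0, 1, 2, 3, 4, 5, 6, 7), n_bins = 4, method = "equal_width")
  expect_equal(as.integer(table(bw)), c(2, 2, 2, 2))
  expect_error(discretize(1:5, n_bins = 1), "n_bins")
})

test_that("categorical weights hit their closed forms", {
  # perfectly separating binary feature, balanced classes of 5+5
  bins <- rep(1:2, each = 5)
  label <- rep(c("a", "b"), each = 5)
  expect_equal(weight_info_gain(bins, label), 1)
  expect_equal(weight_uncertainty(bins, label), 1)
  expect_equal(weight_info_gain_ratio(bins, label), 1)
  expect_equal(weight_chi_squared(bins, label), 10)  # [[5,0],[0,5]], E = 2.5
  expect_equal(weight_gini(bins, label), 0.5)
  expect_equal(weight_rule(bins, label), 0.5)        # accuracy 1 - baseline 0.5

  # independence: identical bin distribution in each class
  bins_i <- rep(c(1, 1, 2, 2), 2)
  label_i <- rep(c("a", "b"), each = 4)
  expect_equal(weight_info_gain(bins_i, label_i), 0)
  expect_equal(weight_gini(bins_i, label_i), 0)
  expect_equal(weight_chi_squared(bins_i, label_i), 0)
  expect_equal(weight_uncertainty(bins_i, label_i), 0)
  expect_equal(weight_rule(bins_i, label_i), 0)

  # one-rule on bins {A: (3,1), B: (1,3)}
  bins_r <- rep(c("A", "B"), each = 4)
  label_r <- c("x", "x", "x", "y", "x", "y", "y", "y")
  expect_equal(weight_rule(bins_r, label_r), 0.25)

  # single-bin feature: all weights 0
  expect_equal(weight_info_gain(rep(1, 8), label_r), 0)
  expect_equal(weight_info_gain_ratio(rep(1, 8), label_r), 0)
  expect_equal(weight_rule(rep(1, 8), label_r), 0)

  expect_error(weight_info_gain(1:3, c("a", "b")), "lengths differ")
})

test_that("ReliefF separates informative from noise features", {
  # constant feature has weight exactly 0
  set.seed(2)
  x <- cbind(const = rep(1, 20), real = rnorm(20))
  w <- suppressWarnings(weight_relief(x, rep(c("a", "b"), 10), k = 5))
  expect_identical(unname(w["const"]), 0)
  expect_true(all(w >= -1 & w <= 1))

  # two separated clusters vs pure noise: informative wins in 100/100 runs
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    lab <- rep(c("a", "b"), each = 20)
    xx <- cbind(inf = rnorm(40, ifelse(lab == "a", 0, 5)), noise = rnorm(40))
    ww <- weight_relief(xx, lab, k = 10)
    ww["inf"] > ww["noise"]
  }, logical(1))
  expect_gte(sum(wins), 99)

  # duplicating every sample preserves the weight ranking
  set.seed(77)
  lab <- rep(c("a", "b"), each = 10)
  xx <- matrix(rnorm(20 * 5), ncol = 5,
               dimnames = list(NULL, paste0("f", 1:5)))
  xx[, 1] <- xx[, 1] + ifelse(lab == "a", 0, 3)
  w1 <- weight_relief(xx, lab, k = 3)
  w2 <- weight_relief(rbind(xx, xx), rep(lab, 2), k = 3)
  expect_equal(order(w1), order(w2))

  # k is truncated to the smallest class size - 1 with a warning
  expect_warning(weight_relief(xx, lab, k = 50), "truncated")
})

test_that("the ensemble normalizes, sums and ranks the seven models", {
  set.seed(5)
  lab <- rep(c("Q331K", "WT"), each = 10)
  x <- matrix(rnorm(20 * 6), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  x[, 3] <- ifelse(lab == "Q331K", 0, 10) + rnorm(20, sd = 0.01)
  rep1 <- weigh_features(x, lab, relief_k = 5)
  expect_s3_class(rep1, "weight_report")
  expect_equal(rep1$ensemble, rowSums(as.matrix(rep1[, paste0(
    "norm_", c("info_gain", "info_gain_ratio", "chi_squared", "gini",
               "uncertainty", "relief", "rule"))])))
  # the dominant feature scores max in every model -> ensemble 7
  expect_equal(rep1$mirna[1], "f3")
  expect_equal(rep1$ensemble[1], 7)
  expect_equal(rep1$rank, 1:6)
  # normalized columns live in [0, 1]
  norms <- as.matrix(rep1[, grep("^norm_", names(rep1))])
  expect_true(all(norms >= 0 & norms <= 1))

  # adding a constant feature changes no other ensemble value
  x2 <- cbind(x, f_const = rep(2, 20))
  rep2 <- weigh_features(x2, lab, relief_k = 5)
  expect_equal(rep2$ensemble[match(rep1$mirna, rep2$mirna)], rep1$ensemble)
  expect_equal(rep2$ensemble[rep2$mirna == "f_const"], 0)

  # scale invariance: multiplying a feature by a constant changes nothing
  x3 <- x; x3[, 2] <- x3[, 2] * 1000
  rep3 <- weigh_features(x3, lab, relief_k = 5)
  expect_equal(rep3$ensemble[match(rep1$mirna, rep3$mirna)], rep1$ensemble,
               tolerance = 1e-9)

  expect_error(weigh_features(x, rep("one", 20)), "2 classes")
})

test_that("label permutation destroys a planted feature's top rank", {
  sim <- planted_simulation(seed = 1, n_features = 100, n_planted = 1,
                            dispersion = 0.05)
  cpm <- cpm_normalize(sim$sim$counts)
  x <- t(log2(as.matrix(cpm[, -1]) + 0.5))
  colnames(x) <- cpm$mirna
  lab <- sim$sim$samples$genotype
  top_true <- weigh_features(x, lab)$mirna[1]
  expect_equal(top_true, sim$planted$mirna)

  # a planted feature stays bimodal after permutation, so chance alignment
  # with a permuted split keeps it highly ranked more often than a null
  # feature would be; the top rank is destroyed in the large majority of
  # permutations and the typical permuted rank is far from the top
  ranks_p <- vapply(1:60, function(s) {
    set.seed(s)
    rep_p <- weigh_features(x, sample(lab))
    rep_p$rank[rep_p$mirna == sim$planted$mirna]
  }, integer(1))
  expect_gte(mean(ranks_p > 10), 0.7)
  expect_gt(median(ranks_p), 10)
})

test_that("confounder scan ranks planted features only under genotype", {
  sim <- planted_simulation(seed = 42)
  scan <- confounder_scan(sim$sim$counts, sim$sim$samples)
  expect_named(scan$reports, c("genotype", "timepoint", "sex"))

  g <- scan$reports$genotype
  planted_ranks <- g$rank[g$mirna %in% sim$planted$mirna]
  expect_true(all(planted_ranks <= 30))

  for (lab in c("timepoint", "sex")) {
    r <- scan$reports[[lab]]
    pl <- r$rank[r$mirna %in% sim$planted$mirna]
    other <- r$rank[!r$mirna %in% sim$planted$mirna]
    p <- wilcox.test(pl, other, alternative = "less")$p.value
    expect_gt(p, 0.01)
  }

  # degenerate labels are skipped with a warning
  s2 <- sim$sim$samples; s2$sex <- "F"
  expect_warning(scan2 <- confounder_scan(sim$sim$counts, s2), "single class")
  expect_false("sex" %in% names(scan2$reports))

  # identical counts for all samples: every weight 0 for every label
  flat <- sim$sim$counts
  for (s in names(flat)[-1]) flat[[s]] <- flat[[2]]
  flat <- evmir:::set_count_units(flat[1:30, ], "raw")
  scan3 <- suppressWarnings(confounder_scan(flat, sim$sim$samples))
  for (r in scan3$reports) expect_true(all(r$ensemble == 0))
})
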