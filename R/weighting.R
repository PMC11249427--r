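#' Discretize a continuous feature
#'
#' Equal-frequency binning places cut points at empirical quantiles
#' (duplicate cut points arising from ties are merged, collapsing bins);
#' equal-width binning spans `[min, max]`. A constant feature yields a
#' single bin, which sends every downstream categorical weight to 0.
#'
#' @param x numeric vector.
#' @param n_bins number of bins (>= 2).
#' @param method `"equal_frequency"` or `"equal_width"`.
#' @return Integer bin labels (1-based) with the cut points as attribute
#'   `"cuts"`.
#' @examples
#' discretize(1:8, n_bins = 4)
#' @export
discretize <- function(x, n_bins = 4L,
                       method = c("equal_frequency", "equal_width")) {
  method <- match.arg(method)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  cuts <- if (method == "equal_frequency") {
    probs <- seq(0, 1, length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
    unique(unname(quantile(x, probs = probs, type = 7)))
  } else {
    if (max(x) == min(x)) numeric(0)
    else seq(min(x), max(x), length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
  }
  # a value equal to a cut point belongs to the lower bin; merged duplicate
  # cut points collapse bins, a constant feature lands in a single bin
  bins <- if (length(cuts) == 0L) rep(1L, length(x)) else
    rowSums(outer(x, cuts, ">")) + 1L
  storage.mode(bins) <- "integer"
  attr(bins, "cuts") <- cuts
  bins
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

gini_impurity <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

check_weight_input <- function(bins, label) {
  if (length(bins) != length(label)) {
    stop("`bins` and `label` lengths differ", call. = FALSE)
  }
}

#' Single-model attribute weights
#'
#' Raw per-feature relevance weights against a class label, one function per
#' model of the seven-model ensemble. The categorical models operate on a
#' discretized feature (see [discretize()]); entropies are in bits.
#'
#' * `weight_info_gain()`: `H(Y) - sum_b p(b) H(Y|b)`.
#' * `weight_info_gain_ratio()`: information gain divided by the bin entropy
#'   `H(B)` (0 when `H(B) = 0`).
#' * `weight_gini()`: Gini impurity decrease
#'   `Gini(Y) - sum_b p(b) Gini(Y|b)`.
#' * `weight_chi_squared()`: Pearson chi-squared statistic
#'   `sum (O - E)^2 / E` over the bin x class table.
#' * `weight_uncertainty()`: symmetric uncertainty
#'   `2 IG / (H(Y) + H(B))` (0 when the denominator is 0).
#' * `weight_rule()`: one-rule accuracy gain — predict the majority class
#'   within each bin; weight = rule accuracy minus the majority-class
#'   baseline, floored at 0.
#'
#' All are non-negative and exactly 0 for a feature whose bin distribution
#' is identical in every class.
#'
#' @param bins integer/factor bin labels from [discretize()].
#' @param label class label vector (same length).
#' @return A single numeric weight.
#' @name single_model_weights
NULL

#' @rdname single_model_weights
#' @export
weight_info_gain <- function(bins, label) {
  check_weight_input(bins, label)
  tab <- table(bins, label)
  h_y <- entropy_bits(colSums(tab))
  p_b <- rowSums(tab) / sum(tab)
  h_cond <- sum(p_b * apply(tab, 1L, entropy_bits))
  max(h_y - h_cond, 0)
}

#' @rdname single_model_weights
#' @export
weight_info_gain_ratio <- function(bins, label) {
  check_weight_input(bins, label)
  h_b <- entropy_bits(table(bins))
  if (h_b == 0) return(0)
  weight_info_gain(bins, label) / h_b
}

#' @rdname single_model_weights
#' @export
weight_gini <- function(bins, label) {
  check_weight_input(bins, label)
  tab <- table(bins, label)
  g_y <- gini_impurity(colSums(tab))
  p_b <- rowSums(tab) / sum(tab)
  g_cond <- sum(p_b * apply(tab, 1L, gini_impurity))
  max(g_y - g_cond, 0)
}

#' @rdname single_model_weights
#' @export
weight_chi_squared <- function(bins, label) {
  check_weight_input(bins, label)
  tab <- table(bins, label)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 1L || ncol(tab) < 1L) return(0)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

#' @rdname single_model_weights
#' @export
weight_uncertainty <- function(bins, label) {
  check_weight_input(bins, label)
  h_y <- entropy_bits(table(label))
  h_b <- entropy_bits(table(bins))
  if (h_y + h_b == 0) return(0)
  2 * weight_info_gain(bins, label) / (h_y + h_b)
}

#' @rdname single_model_weights
#' @export
weight_rule <- function(bins, label) {
  check_weight_input(bins, label)
  tab <- table(bins, label)
  acc <- sum(apply(tab, 1L, max)) / sum(tab)
  baseline <- max(colSums(tab)) / sum(tab)
  max(acc - baseline, 0)
}

#' ReliefF attribute weights
#'
#' ReliefF on continuous features: every instance is visited; its `k`
#' nearest hits (same class) and `k` nearest misses (each other class,
#' prior-weighted) are found by Euclidean distance on range-scaled features;
#' each feature's weight accumulates `diff` to misses minus `diff` to hits,
#' where `diff(a, b) = |a - b| / range`. Weights lie in `[-1, 1]`; a feature
#' constant across samples has weight exactly 0.
#'
#' @param x samples x features matrix or data frame (numeric).
#' @param label class label vector, >= 2 classes with >= 2 samples each.
#' @param k neighbors per class; silently truncated (with a warning) to the
#'   smallest class size minus 1.
#' @return Named numeric vector of weights, one per feature.
#' @export
weight_relief <- function(x, label, k = 10L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  label <- as.factor(label)
  if (nlevels(droplevels(label)) < 2L) {
    stop("`label` must have at least 2 classes", call. = FALSE)
  }
  label <- droplevels(label)
  n <- nrow(x)
  stopifnot(length(label) == n)
  class_sizes <- table(label)
  if (any(class_sizes < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  k_max <- min(class_sizes) - 1L
  if (k > k_max) {
    warning("k truncated from ", k, " to ", k_max, call. = FALSE)
    k <- k_max
  }
  rng <- apply(x, 2L, function(v) diff(range(v)))
  scl <- x
  ok <- rng > 0
  scl[, ok] <- sweep(
    sweep(x[, ok, drop = FALSE], 2L, apply(x[, ok, drop = FALSE], 2L, min)),
    2L, rng[ok], "/")
  scl[, !ok] <- 0
  d <- as.matrix(dist(scl))
  priors <- as.numeric(class_sizes) / n
  names(priors) <- names(class_sizes)
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    for (cl in levels(label)) {
      pool <- which(label == cl & seq_len(n) != i)
      if (length(pool) == 0L) next
      nb <- pool[order(d[i, pool])][seq_len(min(k, length(pool)))]
      diffs <- colSums(abs(sweep(scl[nb, , drop = FALSE], 2L, scl[i, ])))
      if (cl == as.character(label[i])) {
        w <- w - diffs / (n * k)
      } else {
        mult <- priors[cl] / (1 - priors[as.character(label[i])])
        w <- w + mult * diffs / (n * k)
      }
    }
  }
  setNames(w, colnames(x))
}

#' Seven-model attribute-weighting ensemble
#'
#' Runs all seven weighting models (information gain, information gain
#' ratio, chi-squared, Gini index, symmetric uncertainty, ReliefF, one-rule)
#' on every feature and rescales each model's weights to `[0, 1]`, with raw
#' weight 0 anchored at normalized 0 ("non-important") and the column
#' maximum at 1; negative Relief weights (worse than uninformative) floor at
#' 0, and a column with no positive weight maps to all 0. The normalized
#' weights are summed into an ensemble score in `[0, 7]` and features are
#' ranked by it descending, ties broken by feature name.
#'
#' @param x samples x features matrix or data frame with feature names,
#'   typically log2(CPM + 0.5).
#' @param label class label vector (>= 2 classes).
#' @param n_bins,method discretization for the categorical models, see
#'   [discretize()].
#' @param relief_k ReliefF neighbor count.
#' @return A `weight_report` tibble: `mirna`, seven `raw_*` columns, seven
#'   `norm_*` columns, `ensemble`, `rank`, ordered by rank.
#' @seealso [weigh_counts()] for the count-matrix front end.
#' @export
weigh_features <- function(x, label, n_bins = 4L,
                           method = "equal_frequency", relief_k = 10L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("feature_%d", seq_len(ncol(x)))
  }
  label <- droplevels(as.factor(label))
  if (nlevels(label) < 2L) {
    stop("`label` must have at least 2 classes", call. = FALSE)
  }
  models <- c("info_gain", "info_gain_ratio", "chi_squared", "gini",
              "uncertainty", "relief", "rule")
  cat_funs <- list(
    info_gain = weight_info_gain,
    info_gain_ratio = weight_info_gain_ratio,
    chi_squared = weight_chi_squared,
    gini = weight_gini,
    uncertainty = weight_uncertainty,
    rule = weight_rule
  )
  raw <- matrix(0, nrow = ncol(x), ncol = length(models),
                dimnames = list(colnames(x), models))
  for (f in seq_len(ncol(x))) {
    bins <- discretize(x[, f], n_bins = n_bins, method = method)
    for (m in names(cat_funs)) raw[f, m] <- cat_funs[[m]](bins, label)
  }
  raw[, "relief"] <- weight_relief(x, label, k = relief_k)

  # rescale each model's weights to [0, 1] with raw weight 0 anchored at
  # normalized 0 ("non-important") and the column maximum at 1. Negative
  # Relief weights (worse than uninformative) floor at 0. A column with no
  # positive weight maps to all 0.
  norm <- apply(raw, 2L, function(v) {
    hi <- max(v)
    if (hi <= 0) rep(0, length(v)) else pmax(v, 0) / hi
  })
  out <- bind_cols(
    tibble(mirna = rownames(raw)),
    as_tibble(raw, .name_repair = ~ paste0("raw_", models)),
    as_tibble(norm, .name_repair = ~ paste0("norm_", models))
  )
  out$ensemble <- unname(rowSums(norm))
  out <- arrange(out, desc(.data$ensemble), .data$mirna)
  out$rank <- seq_len(nrow(out))
  new_weight_report(out, label_name = NULL)
}

new_weight_report <- function(x, label_name = NULL) {
  attr(x, "label_name") <- label_name
  class(x) <- c("weight_report", class(x))
  x
}

#' Attribute weighting on a count matrix
#'
#' Front end to [weigh_features()]: counts are converted to CPM (unless
#' already normalized), transformed to log2(CPM + 0.5), transposed to
#' samples x features and weighted against a metadata label.
#'
#' @param counts a count tibble (raw or CPM).
#' @param samples sample metadata with a `sample` column and the label
#'   column.
#' @param label name of the metadata column to weight against (e.g.
#'   `"genotype"`).
#' @param ... passed on to [weigh_features()].
#' @return A `weight_report` tibble.
#' @export
weigh_counts <- function(counts, samples, label = "genotype", ...) {
  stopifnot(label %in% names(samples), "sample" %in% names(samples))
  m <- as_count_matrix(counts)
  samples <- samples[match(colnames(m), samples$sample), ]
  if (anyNA(samples$sample)) {
    stop("`samples` must describe every count column", call. = FALSE)
  }
  if (count_units(counts) == "raw") {
    m <- as_count_matrix(cpm_normalize(counts))
  }
  x <- t(log2(m + 0.5))
  rep <- weigh_features(x, samples[[label]], ...)
  attr(rep, "label_name") <- label
  rep
}

#' Scan class labels for confounding structure
#'
#' Runs the attribute-weighting ensemble against each candidate label
#' (genotype, timepoint, sex by default) and reports the overlap between the
#' top-ranked feature sets. On data where only genotype carries an effect,
#' the timepoint and sex reports should rank the affected features no better
#' than chance — the computational check that neither confounds the panel.
#'
#' @param counts a count tibble.
#' @param samples sample metadata.
#' @param labels metadata columns to weight against; single-class labels are
#'   skipped with a warning.
#' @param top_m panel size used for the overlap summary.
#' @param ... passed on to [weigh_counts()].
#' @return A list of class `confounder_scan`: `reports` (one `weight_report`
#'   per label) and `overlap` (pairwise top-`top_m` overlap counts).
#' @export
confounder_scan <- function(counts, samples,
                            labels = c("genotype", "timepoint", "sex"),
                            top_m = 30L, ...) {
  reports <- list()
  for (lab in labels) {
    if (!lab %in% names(samples)) {
      warning("label '", lab, "' not in `samples`; skipped", call. = FALSE)
      next
    }
    cls <- unique(samples[[lab]][samples$sample %in% sample_ids(counts)])
    if (length(cls) < 2L) {
      warning("label '", lab, "' has a single class; skipped", call. = FALSE)
      next
    }
    reports[[lab]] <- weigh_counts(counts, samples, label = lab, ...)
  }
  pairs <- if (length(reports) >= 2L) utils::combn(names(reports), 2L) else NULL
  overlap <- if (is.null(pairs)) {
    tibble(label_a = character(), label_b = character(), overlap = integer())
  } else {
    list_rbind(map(seq_len(ncol(pairs)), function(j) {
      a <- reports[[pairs[1, j]]]; b <- reports[[pairs[2, j]]]
      tibble(
        label_a = pairs[1, j], label_b = pairs[2, j],
        overlap = length(intersect(head(a$mirna, top_m), head(b$mirna, top_m)))
      )
    }))
  }
  structure(list(reports = reports, overlap = overlap, top_m = top_m),
            class = "confounder_scan")
}
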