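#' Expression filter
#'
#' Retains features whose arithmetic mean CPM across all samples is at
#' least `min_mean_rpm` (inclusive: a feature at exactly the threshold is
#' kept). Only features passing this filter enter differential analysis.
#'
#' @param cpm a CPM tibble.
#' @param min_mean_rpm minimum mean reads per million.
#' @return Character vector of retained feature names.
#' @export
filter_expressed <- function(cpm, min_mean_rpm = 5) {
  m <- as_count_matrix(cpm)
  rownames(m)[rowMeans(m) >= min_mean_rpm]
}

#' Per-feature two-group ANOVA
#'
#' One-way fixed-effects ANOVA (pooled variance) per feature on
#' log-transformed expression; for two groups this is the two-sided
#' pooled-variance t-test. Degenerate features (zero variance within both
#' groups) give p = 1 when the group means agree and the smallest positive
#' double (with a warning) when they differ.
#'
#' @param x features x samples numeric matrix (typically log2(CPM + 0.5)),
#'   or a count-style tibble.
#' @param groups group label per sample (2 groups, each n >= 2).
#' @return Named numeric vector of p-values, one per feature.
#' @export
group_test <- function(x, groups) {
  if (is.data.frame(x)) x <- as_count_matrix(x)
  groups <- droplevels(as.factor(groups))
  stopifnot(ncol(x) == length(groups))
  if (nlevels(groups) != 2L || any(table(groups) < 2L)) {
    stop("`groups` must have exactly 2 levels with >= 2 samples each",
         call. = FALSE)
  }
  apply(x, 1L, function(v) {
    vs <- split(v, groups)
    if (all(vapply(vs, var, numeric(1)) == 0)) {
      if (vs[[1]][1] == vs[[2]][1]) return(1)
      warning("zero within-group variance with unequal means; p reported as ",
              "smallest positive double", call. = FALSE)
      return(.Machine$double.xmin)
    }
    oneway.test(v ~ groups, var.equal = TRUE)$p.value
  })
}

#' Benjamini-Hochberg FDR step-up adjustment
#'
#' `adj_(i) = min over j >= i of m * p_(j) / j` on the sorted p-values,
#' capped at 1, returned in the original order.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @examples
#' fdr_step_up(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_step_up <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Signed fold change from a ratio
#'
#' Maps an expression ratio `r` to `r` when `r >= 1` and to `-1/r`
#' otherwise, so `|FC| >= 1` always and the sign gives the direction.
#'
#' @param ratio positive expression ratio(s).
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(2^c(-2.03, 0.98))
#' @export
signed_fold_change <- function(ratio) {
  stopifnot(all(ratio > 0))
  if_else(ratio >= 1, ratio, -1 / ratio)
}

#' Group effect statistics
#'
#' Ratio of within-group geometric means of CPM (pseudocount applied inside
#' the log mean), its log2, and the signed fold change.
#'
#' @param cpm a CPM tibble.
#' @param groups group label per sample.
#' @param case,control group levels compared (`case / control`).
#' @param pseudocount added to every CPM value inside the log.
#' @return A tibble: `mirna`, `ratio`, `log2_ratio`, `fold_change`.
#' @export
effect_stats <- function(cpm, groups, case = "Q331K", control = "WT",
                         pseudocount = 0.5) {
  m <- as_count_matrix(cpm)
  stopifnot(ncol(m) == length(groups))
  i_case <- groups == case
  i_ctrl <- groups == control
  if (!any(i_case) || !any(i_ctrl)) {
    stop("`case`/`control` levels not found in `groups`", call. = FALSE)
  }
  gm_case <- exp(rowMeans(log(m[, i_case, drop = FALSE] + pseudocount)))
  gm_ctrl <- exp(rowMeans(log(m[, i_ctrl, drop = FALSE] + pseudocount)))
  ratio <- gm_case / gm_ctrl
  tibble(
    mirna = rownames(m),
    ratio = unname(ratio),
    log2_ratio = unname(log2(ratio)),
    fold_change = unname(signed_fold_change(ratio))
  )
}

#' Per-feature summary statistics
#'
#' Total, maximum, geometric mean (pseudocount under the log, subtracted
#' back out) and arithmetic mean across all samples.
#'
#' @param x a count tibble (any units).
#' @param pseudocount geometric-mean pseudocount; `0` gives the plain
#'   geometric mean (zero whenever any value is zero).
#' @return A tibble: `mirna`, `total_counts`, `maximum_counts`,
#'   `geometric_mean`, `arithmetic_mean`.
#' @export
summarize_features <- function(x, pseudocount = 0.5) {
  m <- as_count_matrix(x)
  tibble(
    mirna = rownames(m),
    total_counts = unname(rowSums(m)),
    maximum_counts = unname(apply(m, 1L, max)),
    geometric_mean = unname(apply(m, 1L, geometric_mean, pseudocount = pseudocount)),
    arithmetic_mean = unname(rowMeans(m))
  )
}

new_de_table <- function(x, filter = list(), units = "cpm") {
  attr(x, "filter") <- filter
  attr(x, "units") <- units
  class(x) <- c("de_table", setdiff(class(x), "de_table"))
  x
}

#' Differential expression table
#'
#' The full per-feature record for one compartment: summary statistics over
#' all samples, ANOVA p-value on log2(CPM + 0.5) for case vs control,
#' Benjamini-Hochberg FDR step-up, and the ratio / log2(ratio) / signed
#' fold-change triple. Features first pass the mean-CPM expression filter.
#' Note the downstream significance gate uses the raw p-value, not the FDR
#' column: the FDR values are reported for transparency.
#'
#' @param counts a count tibble; raw counts are CPM-normalized on the fly.
#' @param samples sample metadata (`sample` plus the grouping column).
#' @param case,control compared genotype levels.
#' @param group_col metadata column holding the group labels.
#' @param min_mean_rpm expression filter threshold (mean CPM).
#' @param pseudocount pseudocount for geometric means and the log transform.
#' @return A `de_table` tibble ordered by p-value: `mirna`, `total_counts`,
#'   `maximum_counts`, `geometric_mean`, `arithmetic_mean`, `p_value`,
#'   `fdr_step_up`, `ratio`, `log2_ratio`, `fold_change`.
#' @export
de_table <- function(counts, samples, case = "Q331K", control = "WT",
                     group_col = "genotype", min_mean_rpm = 5,
                     pseudocount = 0.5) {
  stopifnot("sample" %in% names(samples), group_col %in% names(samples))
  cpm <- if (count_units(counts) == "raw") cpm_normalize(counts) else counts
  samples <- samples[match(sample_ids(cpm), samples$sample), ]
  if (anyNA(samples$sample)) {
    stop("`samples` must describe every count column", call. = FALSE)
  }
  groups <- samples[[group_col]]
  keep <- filter_expressed(cpm, min_mean_rpm = min_mean_rpm)
  cpm_f <- cpm[match(keep, cpm$mirna), , drop = FALSE]
  cpm_f <- set_count_units(cpm_f, count_units(cpm))
  m <- as_count_matrix(cpm_f)
  in_test <- groups %in% c(case, control)
  p <- group_test(log2(m[, in_test, drop = FALSE] + pseudocount),
                  groups[in_test])
  out <- summarize_features(cpm_f, pseudocount = pseudocount)
  out$p_value <- unname(p)
  out$fdr_step_up <- fdr_step_up(out$p_value)
  out <- left_join(out,
                   effect_stats(cpm_f, groups, case, control, pseudocount),
                   by = "mirna")
  out <- arrange(out, .data$p_value, .data$mirna)
  new_de_table(out,
               filter = list(min_mean_rpm = min_mean_rpm, case = case,
                             control = control, pseudocount = pseudocount),
               units = count_units(cpm))
}

#' Select a significant miRNA panel
#'
#' Applies the significance gate — raw p-value below `alpha` (strict) and
#' absolute signed fold change at or beyond `fc_threshold` (inclusive by
#' default; set `inclusive = FALSE` for a strict comparison) — and orders
#' the surviving features by p-value.
#'
#' @param de a `de_table` (or any tibble with `mirna`, `p_value`,
#'   `fold_change`).
#' @param alpha p-value cutoff (strict `<`).
#' @param fc_threshold absolute fold-change cutoff.
#' @param inclusive whether `|FC|` exactly at the threshold is retained.
#' @param compartment optional compartment label stored with the panel.
#' @return An object of class `mirna_panel`: `compartment`, `features`
#'   (ordered by p), `table` (the retained `de_table` rows) and `filter`
#'   (the thresholds used).
#' @export
select_panel <- function(de, alpha = 0.05, fc_threshold = 1.5,
                         inclusive = TRUE, compartment = NULL) {
  stopifnot(all(c("mirna", "p_value", "fold_change") %in% names(de)))
  stopifnot(alpha >= 0, alpha <= 1, fc_threshold > 0)  # alpha = 0: empty panel
  hit <- de$p_value < alpha &
    (if (inclusive) abs(de$fold_change) >= fc_threshold
     else abs(de$fold_change) > fc_threshold)
  tab <- arrange(de[hit, , drop = FALSE], .data$p_value, .data$mirna)
  structure(
    list(
      compartment = compartment,
      features = tab$mirna,
      table = as_tibble(tab),
      filter = list(alpha = alpha, fc_threshold = fc_threshold,
                    inclusive = inclusive)
    ),
    class = "mirna_panel"
  )
}

#' @export
print.mirna_panel <- function(x, ...) {
  cat(sprintf(
    "<mirna_panel>%s %d miRNAs (p < %g, |FC| %s %g)\n",
    if (is.null(x$compartment)) "" else paste0(" [", x$compartment, "]"),
    length(x$features), x$filter$alpha,
    if (x$filter$inclusive) ">=" else ">", x$filter$fc_threshold
  ))
  if (length(x$features) > 0L) {
    cat(paste(strwrap(paste(x$features, collapse = ", "), width = 76),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
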