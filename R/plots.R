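#' Plot methods for evmir results
#'
#' ggplot2 `autoplot()` methods: a PCA score plot with flagged outliers for
#' [pca_qc()] results, a top-feature ensemble-weight bar chart for
#' [weigh_features()] reports, and a volcano plot for [de_table()] results.
#'
#' @param object an evmir result object.
#' @param top_k number of top-ranked features shown (weight reports).
#' @param alpha,fc_threshold significance thresholds drawn on the volcano.
#' @param ... unused.
#' @return A ggplot object.
#' @name evmir_plots
NULL

#' @rdname evmir_plots
#' @export
autoplot.pca_qc <- function(object, ...) {
  sc <- object$scores
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2, colour = .data$outlier)) +
    geom_point(size = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = "outlier",
      title = "PCA sample QC (log2 CPM)"
    ) +
    theme_bw()
}

#' @rdname evmir_plots
#' @export
autoplot.weight_report <- function(object, top_k = 30L, ...) {
  top <- head(arrange(as_tibble(object), .data$rank), top_k)
  top$mirna <- factor(top$mirna, levels = rev(top$mirna))
  ggplot(top, aes(x = .data$ensemble, y = .data$mirna)) +
    geom_col(fill = "steelblue") +
    labs(x = "ensemble weight (sum of 7 normalized models, 0-7)",
         y = NULL, title = "Attribute-weighting ensemble") +
    theme_bw()
}

#' @rdname evmir_plots
#' @export
autoplot.de_table <- function(object, alpha = 0.05, fc_threshold = 1.5, ...) {
  d <- as_tibble(object)
  d$significant <- d$p_value < alpha & abs(d$fold_change) >= fc_threshold
  ggplot(d, aes(x = .data$log2_ratio, y = -log10(.data$p_value),
                colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_vline(xintercept = c(-log2(fc_threshold), log2(fc_threshold)),
               linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "log2(ratio)", y = "-log10(p)", colour = "panel",
         title = "Differential miRNA expression") +
    theme_bw()
}
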