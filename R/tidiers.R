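#' Tidy and glance methods for evmir result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per sample for normalization/QC, per feature for weights and DE, per
#' region for Venn counts); `glance()` returns a one-row summary.
#'
#' @param x an evmir result object.
#' @param ... unused.
#' @return A tibble.
#' @name evmir_tidiers
NULL

#' @rdname evmir_tidiers
#' @export
tidy.tmm_norm <- function(x, ...) x$factors

#' @rdname evmir_tidiers
#' @export
glance.tmm_norm <- function(x, ...) {
  tibble(
    n_samples = nrow(x$factors),
    ref_sample = x$ref_sample,
    factor_geometric_mean = exp(mean(log(x$factors$tmm_factor))),
    trim_m = x$trim_m,
    trim_a = x$trim_a
  )
}

#' @rdname evmir_tidiers
#' @export
tidy.pca_qc <- function(x, ...) x$scores

#' @rdname evmir_tidiers
#' @export
glance.pca_qc <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    k = x$k,
    var_explained_pc1 = x$var_explained[1],
    var_explained_pc2 = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_,
    n_flagged = length(x$flagged)
  )
}

#' @rdname evmir_tidiers
#' @export
tidy.weight_report <- function(x, ...) as_tibble(x)

#' @rdname evmir_tidiers
#' @export
glance.weight_report <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    label = attr(x, "label_name") %||% NA_character_,
    max_ensemble = max(x$ensemble),
    top_feature = x$mirna[which.max(x$ensemble)]
  )
}

#' @rdname evmir_tidiers
#' @export
tidy.de_table <- function(x, ...) as_tibble(x)

#' @rdname evmir_tidiers
#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_p05 = sum(x$p_value < 0.05),
    n_fdr05 = sum(x$fdr_step_up < 0.05),
    min_p = min(x$p_value)
  )
}

#' @rdname evmir_tidiers
#' @export
tidy.mirna_panel <- function(x, ...) x$table

#' @rdname evmir_tidiers
#' @export
glance.mirna_panel <- function(x, ...) {
  tibble(
    compartment = x$compartment %||% NA_character_,
    n_mirnas = length(x$features),
    n_up = sum(x$table$fold_change > 0),
    n_down = sum(x$table$fold_change < 0),
    alpha = x$filter$alpha,
    fc_threshold = x$filter$fc_threshold,
    inclusive = x$filter$inclusive
  )
}

#' @rdname evmir_tidiers
#' @export
tidy.confounder_scan <- function(x, ...) {
  list_rbind(imap(x$reports, function(rep, lab) {
    mutate(as_tibble(rep), label = lab, .before = 1L)
  }))
}

#' @rdname evmir_tidiers
#' @export
glance.confounder_scan <- function(x, ...) {
  tibble(n_labels = length(x$reports), top_m = x$top_m)
}
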