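#' Intersect two compartment panels
#'
#' The common-miRNA table: one row per (common miRNA, compartment) carrying
#' that compartment's differential-expression statistics, plus a
#' direction-agreement flag (same fold-change sign in both compartments).
#'
#' @param panel_a,panel_b `mirna_panel` objects from [select_panel()],
#'   sharing a feature namespace. Names are matched by exact string equality
#'   after trimming whitespace; e.g. `-486a` and `-486b` are distinct.
#' @return A `common_table` tibble: `mirna`, `compartment`,
#'   `direction_agreement`, then the statistics columns present in both
#'   panel tables. Empty when the panels are disjoint.
#' @export
intersect_panels <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "mirna_panel"), inherits(panel_b, "mirna_panel"))
  fa <- trimws(panel_a$features)
  fb <- trimws(panel_b$features)
  common <- fa[fa %in% fb]
  lab_a <- panel_a$compartment %||% "panel_a"
  lab_b <- panel_b$compartment %||% "panel_b"
  if (length(common) == 0L) {
    out <- tibble(mirna = character(), compartment = character(),
                  direction_agreement = logical())
    class(out) <- c("common_table", class(out))
    return(out)
  }
  ta <- panel_a$table[match(common, trimws(panel_a$table$mirna)), ]
  tb <- panel_b$table[match(common, trimws(panel_b$table$mirna)), ]
  agree <- sign(ta$fold_change) == sign(tb$fold_change)
  stats_cols <- intersect(names(ta), names(tb))
  stats_cols <- setdiff(stats_cols, "mirna")
  out <- bind_rows(
    bind_cols(tibble(mirna = common, compartment = lab_a,
                     direction_agreement = agree),
              ta[, stats_cols]),
    bind_cols(tibble(mirna = common, compartment = lab_b,
                     direction_agreement = agree),
              tb[, stats_cols])
  )
  out <- arrange(out, .data$mirna, .data$compartment)
  class(out) <- c("common_table", class(out))
  out
}

#' Venn counts for two panels
#'
#' Partition of the union of two panels' feature sets.
#'
#' @inheritParams intersect_panels
#' @return A one-row tibble: `only_a`, `only_b`, `both`.
#' @export
venn_counts <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "mirna_panel"), inherits(panel_b, "mirna_panel"))
  fa <- unique(trimws(panel_a$features))
  fb <- unique(trimws(panel_b$features))
  both <- length(intersect(fa, fb))
  tibble(only_a = length(fa) - both, only_b = length(fb) - both, both = both)
}
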