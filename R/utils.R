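# Internal helpers shared across modules.

# Validate that every element of `x` is a nucleotide string; errors name the
# offending position and element.
validate_nucleotides <- function(x, allow_n = FALSE, arg = "sequence") {
  pat <- if (allow_n) "[^ACGTUNacgtun]" else "[^ACGTUacgtu]"
  pos <- regexpr(pat, x)
  bad <- which(pos > 0L)
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop(sprintf(
      "invalid nucleotide '%s' at position %d of %s %d",
      substr(x[i], pos[i], pos[i]), pos[i], arg, i
    ), call. = FALSE)
  }
  invisible(x)
}

to_dna <- function(x) chartr("Uu", "Tt", x)
to_rna <- function(x) chartr("Tt", "Uu", x)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- count table helpers ----------------------------------------------------
# Counts travel as a tibble whose first column ("mirna") names the feature and
# whose remaining columns are one numeric column per sample. A "units"
# attribute records the scale: "raw", "cpm" or "tmm_cpm".

count_units <- function(counts) attr(counts, "units") %||% "raw"

set_count_units <- function(counts, units) {
  units <- match.arg(units, c("raw", "cpm", "tmm_cpm"))
  attr(counts, "units") <- units
  counts
}

assert_count_tbl <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    stop("`counts` must be a data frame: one feature column then one numeric column per sample",
         call. = FALSE)
  }
  if (!is.character(counts[[1L]]) && !is.factor(counts[[1L]])) {
    stop("the first column of `counts` must hold feature names", call. = FALSE)
  }
  invisible(counts)
}

as_count_matrix <- function(counts) {
  assert_count_tbl(counts)
  m <- as.matrix(counts[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1L]])
  m
}

as_count_tbl <- function(m, units = "raw", feature_col = "mirna") {
  out <- as_tibble(m, rownames = feature_col)
  set_count_units(out, units)
}

sample_ids <- function(counts) colnames(counts)[-1L]

# Geometric mean with a pseudocount applied inside the log and subtracted
# back out (floored at zero); pseudocount = 0 gives the plain geometric mean.
geometric_mean <- function(x, pseudocount = 0.5) {
  g <- exp(mean(log(x + pseudocount))) - pseudocount
  max(g, 0)
}
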