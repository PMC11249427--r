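#' Counts-per-million normalization
#'
#' Scales each sample to counts per million reads: `cpm = count / library
#' size * 1e6`. By default library sizes are the raw column sums; effective
#' library sizes (e.g. raw sizes times TMM factors) may be supplied instead,
#' which is how TMM normalization enters CPM space.
#'
#' @param counts a raw count tibble (feature column `mirna`, one column per
#'   sample).
#' @param library_sizes optional named vector of library sizes per sample;
#'   default: column sums of `counts`.
#' @return A CPM tibble (units `"cpm"`).
#' @examples
#' m <- tibble::tibble(mirna = c("a", "b"), s1 = c(5, 999995), s2 = c(1, 1))
#' cpm_normalize(m)
#' @export
cpm_normalize <- function(counts, library_sizes = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(library_sizes)) {
    library_sizes <- colSums(m)
  } else {
    if (!is.null(names(library_sizes))) {
      library_sizes <- library_sizes[colnames(m)]
    }
    stopifnot(length(library_sizes) == ncol(m))
  }
  zero <- which(library_sizes <= 0 | !is.finite(library_sizes))
  if (length(zero) > 0L) {
    stop("zero or invalid library size for sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  as_count_tbl(sweep(m, 2L, library_sizes, "/") * 1e6, units = "cpm")
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference sample,
#' per-feature log2 expression ratios (M) and average log2 abundances (A)
#' are computed on library-scaled proportions over features expressed in
#' both; the M values are doubly trimmed (by M and by A) and averaged with
#' inverse-asymptotic-variance weights; the scaling factor is 2 to that
#' weighted mean, and factors are rescaled to geometric mean 1. The
#' reference sample is the one whose upper quartile of scaled counts is
#' closest to the mean upper quartile.
#'
#' @param counts a raw count tibble.
#' @param trim_m two-sided trim fraction on M values (default 0.30).
#' @param trim_a two-sided trim fraction on A values (default 0.05).
#' @return An object of class `tmm_norm`: `factors` (tibble: sample, tmm
#'   factor, library size, effective library size), `cpm` (TMM-CPM tibble
#'   computed on effective library sizes), `ref_sample`, `trim_m`, `trim_a`.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization method
#'   for differential expression analysis of RNA-seq data. Genome Biology
#'   11:R25.
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  # reference: upper quartile of scaled counts closest to the mean
  f75 <- apply(sweep(m, 2L, lib, "/"), 2L, quantile, probs = 0.75)
  ref_idx <- which.min(abs(f75 - mean(f75)))
  ref <- m[, ref_idx]
  lib_ref <- lib[ref_idx]

  factors <- vapply(seq_len(ncol(m)), function(s) {
    obs <- m[, s]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) {
      stop("sample '", colnames(m)[s],
           "' shares no expressed features with the reference", call. = FALSE)
    }
    o <- obs[keep] / lib[s]
    r <- ref[keep] / lib_ref
    M <- log2(o / r)
    A <- 0.5 * log2(o * r)
    w <- (lib[s] - obs[keep]) / (lib[s] * obs[keep]) +
      (lib_ref - ref[keep]) / (lib_ref * ref[keep])
    fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (length(M) == 0L) return(1)
    if (max(abs(M)) < 1e-10) return(1)  # identical composition
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rk_m <- rank(M); rk_a <- rank(A)
    keep2 <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
    if (!any(keep2)) return(1)
    f <- 2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
    if (!is.finite(f) || f <= 0) 1 else f
  }, numeric(1))

  factors <- factors / exp(mean(log(factors)))  # geometric mean 1
  eff <- lib * factors
  fct <- tibble(
    sample = colnames(m),
    tmm_factor = unname(factors),
    library_size = unname(lib),
    effective_library_size = unname(eff)
  )
  structure(
    list(
      factors = fct,
      cpm = cpm_normalize(counts, library_sizes = setNames(eff, colnames(m))),
      ref_sample = colnames(m)[ref_idx],
      trim_m = trim_m,
      trim_a = trim_a
    ),
    class = "tmm_norm"
  )
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat(sprintf("<tmm_norm> %d samples, reference '%s', trim (M %.2f, A %.2f)\n",
              nrow(x$factors), x$ref_sample, x$trim_m, x$trim_a))
  print(x$factors)
  invisible(x)
}

#' PCA-based sample quality control
#'
#' Expression is transformed to log2(CPM + 0.5) and feature-centered, then
#' decomposed by SVD. Each sample's Euclidean distance from the score-space
#' centroid over the first `k` components is converted to a robust z-score;
#' a sample is flagged when its distance exceeds the median distance by more
#' than `flag_sd` times the robust SD (median absolute deviation x 1.4826)
#' of all distances.
#'
#' @param cpm a CPM tibble (see [cpm_normalize()]).
#' @param k number of principal components used for scoring/flagging.
#' @param flag_sd flagging threshold in robust SDs; `Inf` disables flagging.
#' @return An object of class `pca_qc`: `scores` (tibble: sample, PC scores,
#'   distance, outlier flag), `var_explained` (fractions per component),
#'   `flagged` (sample ids), `k`, `flag_sd`.
#' @export
pca_qc <- function(cpm, k = 2L, flag_sd = 3.0) {
  m <- as_count_matrix(cpm)
  if (ncol(m) < 3L) stop("PCA QC needs at least 3 samples", call. = FALSE)
  if (k > min(dim(m))) {
    stop("k = ", k, " exceeds min(features, samples) = ", min(dim(m)),
         call. = FALSE)
  }
  lg <- log2(m + 0.5)
  centered <- lg - rowMeans(lg)
  sv <- svd(t(centered))           # samples x features
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  var_explained <- sv$d^2 / sum(sv$d^2)
  sc <- scores[, seq_len(k), drop = FALSE]
  centroid <- colMeans(sc)
  dist_c <- sqrt(rowSums(sweep(sc, 2L, centroid)^2))
  robust_sd <- mad(dist_c)
  flags <- if (!is.finite(flag_sd)) {
    rep(FALSE, length(dist_c))
  } else {
    dist_c > median(dist_c) + flag_sd * robust_sd
  }
  score_tbl <- as_tibble(sc, .name_repair = ~ paste0("PC", seq_len(k)))
  score_tbl <- bind_cols(tibble(sample = colnames(m)), score_tbl)
  score_tbl$distance <- dist_c
  score_tbl$outlier <- flags
  structure(
    list(scores = score_tbl,
         var_explained = var_explained,
         flagged = colnames(m)[flags],
         k = k, flag_sd = flag_sd),
    class = "pca_qc"
  )
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(sprintf("<pca_qc> %d samples, k = %d, flag_sd = %s; %d flagged\n",
              nrow(x$scores), x$k, format(x$flag_sd), length(x$flagged)))
  if (length(x$flagged) > 0L) cat("flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
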