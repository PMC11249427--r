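#' Read and write sequence and table formats
#'
#' Thin tibble-first wrappers around Biostrings (FASTA/FASTQ) and readr (TSV)
#' so every pipeline stage exchanges plain tables. Count tables are written
#' with the sample ids as the header row and the feature name as the first
#' column; a leading `#`-comment records the units and conventions.
#'
#' @param path file path.
#' @param x,counts,reads tibble to write (see individual functions).
#' @param units units tag attached to a count table read from disk
#'   (`"raw"`, `"cpm"` or `"tmm_cpm"`).
#' @param comments character vector of comment lines (written prefixed
#'   with `"# "`).
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name evmir_io
NULL

#' @rdname evmir_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(name = names(ss), sequence = as.character(ss))
}

#' @rdname evmir_io
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  ss <- Biostrings::BStringSet(setNames(as.character(x[[2L]]), as.character(x[[1L]])))
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80L)
  invisible(path)
}

#' @rdname evmir_io
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(ss),
    sequence = as.character(ss),
    quality = as.character(S4Vectors::mcols(ss)$qualities)
  )
}

#' @rdname evmir_io
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence", "quality") %in% names(reads)))
  ss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qs <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' @rdname evmir_io
#' @export
read_counts_tsv <- function(path, units = "raw") {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(x)[1L] <- "mirna"
  set_count_units(x, units)
}

#' @rdname evmir_io
#' @export
write_counts_tsv <- function(counts, path) {
  assert_count_tbl(counts)
  write_tsv_commented(counts, path,
                      comments = sprintf("units: %s", count_units(counts)))
}

#' @rdname evmir_io
#' @export
write_tsv_commented <- function(x, path, comments = character()) {
  if (length(comments) > 0L) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Bundled EV miRNA panel statistics
#'
#' Per-miRNA differential-expression statistics for the brain-derived EV
#' (BDEV) and serum EV compartments of a published TDP-43*Q331K vs
#' TDP-43*WT mouse study, shipped as worked-example input. Columns follow
#' the [de_table()] schema: total/maximum counts, geometric and arithmetic
#' means (CPM units), ANOVA p-value, Benjamini-Hochberg FDR step-up, ratio,
#' log2(ratio) and signed fold change.
#'
#' @param compartment `"bdev"` or `"serum"`.
#' @return A tibble with one row per panel miRNA.
#' @examples
#' published_panel_stats("serum")
#' @export
published_panel_stats <- function(compartment = c("bdev", "serum")) {
  compartment <- match.arg(compartment)
  path <- system.file("extdata", paste0(compartment, "_panel_stats.tsv"),
                      package = "evmir", mustWork = TRUE)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  new_de_table(x, filter = list(min_mean_rpm = 5), units = "cpm")
}
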