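#' IsomiR-tolerant alignment policy
#'
#' Bounds for matching a trimmed read against a mature miRNA: at most
#' `max_mismatches` substitutions within the aligned core, and terminal
#' (isomiR) variants of at most 2 bases per category by default — additional
#' 5'/3' bases on the read, or missing 5'/3' reference bases. Extra terminal
#' read bases are unconstrained in content and never counted as mismatches.
#'
#' @param max_mismatches maximum substitutions within the aligned core.
#' @param max_add5,max_add3 maximum additional (upstream/downstream) read
#'   bases beyond the mature ends.
#' @param max_miss5,max_miss3 maximum missing (upstream/downstream) mature
#'   bases not covered by the read.
#' @param min_length reads shorter than this after trimming are flagged
#'   `too_short` and never aligned.
#' @param ambiguous what to do with reads tied between references:
#'   `"discard"` (status `ambiguous`, counted nowhere) or `"first_by_name"`
#'   (assign to the lexicographically first reference).
#' @return An object of class `alignment_policy`.
#' @export
alignment_policy <- function(max_mismatches = 2L,
                             max_add5 = 2L, max_add3 = 2L,
                             max_miss5 = 2L, max_miss3 = 2L,
                             min_length = 15L,
                             ambiguous = c("discard", "first_by_name")) {
  ambiguous <- match.arg(ambiguous)
  vals <- c(max_mismatches, max_add5, max_add3, max_miss5, max_miss3, min_length)
  if (any(vals < 0L)) stop("policy bounds must be >= 0", call. = FALSE)
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         max_add5 = as.integer(max_add5), max_add3 = as.integer(max_add3),
         max_miss5 = as.integer(max_miss5), max_miss3 = as.integer(max_miss3),
         min_length = as.integer(min_length), ambiguous = ambiguous),
    class = "alignment_policy"
  )
}

#' Trim a 3' adapter from reads
#'
#' Finds the leftmost occurrence of the adapter: at each read position the
#' adapter prefix is compared with the remaining read suffix; an occurrence
#' requires an overlap of at least `min_overlap` bases (or the full adapter)
#' with a mismatch fraction of at most `max_error_rate`. Everything from the
#' occurrence onward is removed; reads without an occurrence are returned
#' unchanged.
#'
#' @param sequences character vector of reads (DNA, `N` allowed).
#' @param adapter adapter sequence (DNA).
#' @param min_overlap minimum adapter/read overlap at the read's 3' end.
#' @param max_error_rate maximum mismatch fraction within the overlap.
#' @return Character vector of trimmed reads.
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACTGGAATTCTCGG", "TGGAATTCTCGG")
#' @export
trim_adapter <- function(sequences, adapter, min_overlap = 8L,
                         max_error_rate = 0.125) {
  if (!nzchar(adapter)) stop("`adapter` must be non-empty", call. = FALSE)
  validate_nucleotides(adapter, arg = "adapter")
  a_raw <- charToRaw(toupper(adapter))
  na <- length(a_raw)
  vapply(sequences, function(read) {
    nr <- nchar(read)
    if (nr == 0L) return("")
    r_raw <- charToRaw(toupper(read))
    for (i in seq_len(nr)) {
      len <- min(nr - i + 1L, na)
      if (len < min_overlap && len < na) next
      mism <- sum(r_raw[i:(i + len - 1L)] != a_raw[seq_len(len)])
      if (mism <= floor(len * max_error_rate)) {
        return(substr(read, 1L, i - 1L))
      }
    }
    read
  }, character(1), USE.NAMES = FALSE)
}

# Enumerate candidate alignments of one read against one reference and
# return the best as c(mismatches, add5, add3, miss5, miss3), or NULL.
# Best = fewest mismatches, then fewest total end variants, then smallest
# add5 (canonical-form preference).
align_to_one <- function(r_raw, m_raw, policy) {
  nr <- length(r_raw)
  nm <- length(m_raw)
  best <- NULL
  for (miss5 in 0:policy$max_miss5) {
    for (miss3 in 0:policy$max_miss3) {
      core_len <- nm - miss5 - miss3
      if (core_len < 1L) next
      m_core <- m_raw[(miss5 + 1L):(nm - miss3)]
      for (add5 in 0:policy$max_add5) {
        add3 <- nr - add5 - core_len
        if (add3 < 0L || add3 > policy$max_add3) next
        mism <- sum(r_raw[(add5 + 1L):(add5 + core_len)] != m_core)
        if (mism > policy$max_mismatches) next
        cand <- c(mism, add5, add3, miss5, miss3)
        if (is.null(best)) {
          best <- cand
        } else {
          mods_c <- add5 + add3 + miss5 + miss3
          mods_b <- sum(best[2:5])
          if (mism < best[1] ||
              (mism == best[1] && mods_c < mods_b) ||
              (mism == best[1] && mods_c == mods_b && add5 < best[2])) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

#' Align trimmed reads to a mature-miRNA reference
#'
#' A read aligns to a mature sequence if it can be decomposed as
#' `add5 extra bases + core + add3 extra bases`, where the core matches the
#' mature sequence minus `miss5`/`miss3` terminal bases, all four terminal
#' variants within the policy bounds and core substitutions within
#' `max_mismatches`. The best candidate minimizes (mismatches, total
#' terminal variants); reads tied between different references are
#' `ambiguous` under the discard policy. U and T are interchangeable in
#' both reads and reference.
#'
#' @param reads character vector of trimmed read sequences, or a tibble with
#'   columns `read_id` and `sequence`.
#' @param reference tibble with columns `mirna` and `sequence`.
#' @param policy an [alignment_policy()].
#' @return A tibble with one row per read: `read_id`, `mirna` (NA unless
#'   assigned), `n_mismatches`, `add5`, `add3`, `miss5`, `miss3`, `status`
#'   (`assigned`, `unaligned`, `too_short` or `ambiguous`).
#' @export
align_reads <- function(reads, reference, policy = alignment_policy()) {
  stopifnot(inherits(policy, "alignment_policy"))
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%d", seq_along(reads)),
                    sequence = reads)
  }
  if (nrow(reference) == 0L) stop("`reference` is empty", call. = FALSE)
  # lexicographic reference order makes first_by_name deterministic
  ord <- order(reference$mirna, method = "radix")
  ref_names <- reference$mirna[ord]
  ref_raw <- lapply(toupper(to_dna(reference$sequence[ord])), charToRaw)

  n <- nrow(reads)
  out_mirna <- rep(NA_character_, n)
  out_mm <- rep(NA_integer_, n)
  out_ev <- matrix(NA_integer_, nrow = n, ncol = 4L)
  out_status <- character(n)

  for (i in seq_len(n)) {
    seq_i <- toupper(to_dna(reads$sequence[i]))
    if (nchar(seq_i) < policy$min_length) {
      out_status[i] <- "too_short"
      next
    }
    r_raw <- charToRaw(seq_i)
    best <- NULL; best_ref <- NA_integer_; tie <- FALSE
    for (j in seq_along(ref_raw)) {
      cand <- align_to_one(r_raw, ref_raw[[j]], policy)
      if (is.null(cand)) next
      if (is.null(best)) {
        best <- cand; best_ref <- j; tie <- FALSE
      } else {
        key_c <- c(cand[1], sum(cand[2:5]))
        key_b <- c(best[1], sum(best[2:5]))
        if (key_c[1] < key_b[1] ||
            (key_c[1] == key_b[1] && key_c[2] < key_b[2])) {
          best <- cand; best_ref <- j; tie <- FALSE
        } else if (identical(key_c, key_b)) {
          tie <- TRUE
        }
      }
    }
    if (is.null(best)) {
      out_status[i] <- "unaligned"
    } else if (tie && policy$ambiguous == "discard") {
      out_status[i] <- "ambiguous"
    } else {
      out_status[i] <- "assigned"
      out_mirna[i] <- ref_names[best_ref]
      out_mm[i] <- best[1]
      out_ev[i, ] <- best[2:5]
    }
  }
  tibble(
    read_id = reads$read_id,
    mirna = out_mirna,
    n_mismatches = out_mm,
    add5 = out_ev[, 1], add3 = out_ev[, 2],
    miss5 = out_ev[, 3], miss3 = out_ev[, 4],
    status = out_status
  )
}

#' Quantify small RNA reads into a raw count matrix
#'
#' Optionally trims the 3' adapter, aligns every read of every sample with
#' [align_reads()], and tallies assigned reads per (miRNA, sample). Samples
#' with zero assigned reads are kept as all-zero columns and flagged with a
#' warning for QC.
#'
#' @param read_sets a named list (sample id -> reads): each element either a
#'   tibble with `read_id`/`sequence` columns or a path to a FASTQ file.
#' @param reference tibble with columns `mirna` and `sequence`.
#' @param adapter optional 3' adapter to trim before alignment.
#' @param policy an [alignment_policy()].
#' @return A list: `counts` (raw count tibble, all reference features as
#'   rows), `summary` (per-sample read tallies by status) and `assignments`
#'   (per-read outcome tables).
#' @export
quantify_reads <- function(read_sets, reference, adapter = NULL,
                           policy = alignment_policy()) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)),
            all(nzchar(names(read_sets))))
  features <- sort(reference$mirna, method = "radix")
  counts <- matrix(0, nrow = length(features), ncol = length(read_sets),
                   dimnames = list(features, names(read_sets)))
  summaries <- vector("list", length(read_sets))
  assignments <- vector("list", length(read_sets))
  for (s in seq_along(read_sets)) {
    reads <- read_sets[[s]]
    if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
    if (!is.null(adapter)) {
      reads$sequence <- trim_adapter(reads$sequence, adapter)
    }
    asn <- align_reads(reads[, c("read_id", "sequence")], reference, policy)
    tab <- table(factor(asn$mirna[asn$status == "assigned"], levels = features))
    counts[, s] <- as.numeric(tab)
    if (sum(counts[, s]) == 0) {
      warning("sample '", names(read_sets)[s],
              "' has zero assigned reads; kept as all-zero column",
              call. = FALSE)
    }
    summaries[[s]] <- tibble(
      sample = names(read_sets)[s],
      n_reads = nrow(asn),
      assigned = sum(asn$status == "assigned"),
      unaligned = sum(asn$status == "unaligned"),
      too_short = sum(asn$status == "too_short"),
      ambiguous = sum(asn$status == "ambiguous")
    )
    assignments[[s]] <- asn
  }
  list(
    counts = as_count_tbl(counts, units = "raw"),
    summary = list_rbind(summaries),
    assignments = setNames(assignments, names(read_sets))
  )
}
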