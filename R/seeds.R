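#' Nucleotide complement and reverse complement
#'
#' Watson-Crick complement per position; `reverse_complement()` additionally
#' reverses. RNA and DNA are both accepted (U and T are interchangeable on
#' input) and the output alphabet follows the input: a sequence containing U
#' complements to RNA, otherwise to DNA. Case is preserved.
#'
#' @param x character vector of sequences.
#' @return Character vector of the same length.
#' @examples
#' complement("UGUGAGG")         # "ACACUCC"
#' reverse_complement("GGAGUGU") # "ACACUCC"
#' @export
complement <- function(x) {
  validate_nucleotides(x, arg = "sequence")
  comp_dna <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  is_rna <- grepl("[Uu]", x)
  out <- comp_dna
  out[is_rna] <- to_rna(comp_dna[is_rna])
  out
}

#' @rdname complement
#' @export
reverse_complement <- function(x) {
  vapply(strsplit(complement(x), ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a miRNA seed
#'
#' The canonical seed region: positions 2-8 (1-based, inclusive) of the
#' mature sequence read 5' to 3', a 7-nt string.
#'
#' @param x mature sequence(s), length >= 8 nt.
#' @param start,end 1-based inclusive seed coordinates.
#' @return Character vector of seeds.
#' @examples
#' extract_seed("UGGAGUGUGACAAUGGUGUUUG")  # "GGAGUGU"
#' @export
extract_seed <- function(x, start = 2L, end = 8L) {
  validate_nucleotides(x, arg = "sequence")
  short <- nchar(x) < end
  if (any(short)) {
    stop("sequence ", which(short)[1], " is shorter than ", end, " nt",
         call. = FALSE)
  }
  substr(x, start, end)
}

#' Scan 3'UTR sequences for exact seed-match sites
#'
#' A site is an exact occurrence of the reverse complement of a miRNA's
#' seed (positions 2-8) on the UTR plus strand. All occurrences are
#' reported, overlapping ones included, with 1-based inclusive start
#' coordinates, in deterministic (miRNA, UTR, start) order. Scanning is
#' invariant to U/T representation of either input.
#'
#' @param mirnas mature miRNAs: a tibble with columns `mirna` and
#'   `sequence`, or a named character vector.
#' @param utrs 3'UTR sequences: a tibble with columns `utr` and `sequence`,
#'   or a named character vector.
#' @return A tibble: `mirna`, `utr`, `start`, `site` (7-nt site sequence in
#'   the UTR's alphabet), `type` (`"7mer"`).
#' @export
find_seed_sites <- function(mirnas, utrs) {
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna = names(mirnas), sequence = unname(mirnas))
  }
  if (!is.data.frame(utrs)) {
    utrs <- tibble(utr = names(utrs), sequence = unname(utrs))
  }
  names(mirnas)[1:2] <- c("mirna", "sequence")
  names(utrs)[1:2] <- c("utr", "sequence")
  validate_nucleotides(mirnas$sequence, arg = "miRNA")
  validate_nucleotides(utrs$sequence, arg = "UTR")
  seeds <- extract_seed(toupper(mirnas$sequence))
  sites_dna <- to_dna(reverse_complement(seeds))
  utr_dna <- lapply(toupper(to_dna(utrs$sequence)), Biostrings::DNAString)
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    pat <- Biostrings::DNAString(sites_dna[i])
    for (j in seq_len(nrow(utrs))) {
      hits <- Biostrings::matchPattern(pat, utr_dna[[j]])
      starts <- Biostrings::start(hits)
      if (length(starts) == 0L) next
      rows[[length(rows) + 1L]] <- tibble(
        mirna = mirnas$mirna[i],
        utr = utrs$utr[j],
        start = as.integer(starts),
        site = substr(rep(utrs$sequence[j], length(starts)),
                      starts, starts + 6L),
        type = "7mer"
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(mirna = character(), utr = character(),
                  start = integer(), site = character(), type = character()))
  }
  arrange(list_rbind(rows), .data$mirna, .data$utr, .data$start)
}

#' UTRs targeted by many miRNAs
#'
#' Groups seed sites by UTR, counts distinct targeting miRNAs and keeps
#' UTRs exceeding the threshold (strict `>` comparison).
#'
#' @param sites a site table from [find_seed_sites()].
#' @param min_mirnas threshold; a UTR is kept when targeted by strictly more
#'   than this many distinct miRNAs.
#' @return A tibble `utr`, `n_mirnas`, ordered by count descending.
#' @export
shared_targets <- function(sites, min_mirnas) {
  stopifnot(all(c("mirna", "utr") %in% names(sites)))
  out <- summarise(group_by(sites, .data$utr),
                   n_mirnas = n_distinct(.data$mirna), .groups = "drop")
  out <- filter(out, .data$n_mirnas > min_mirnas)
  arrange(out, desc(.data$n_mirnas), .data$utr)
}
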