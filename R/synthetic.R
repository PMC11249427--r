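#' Describe a synthetic EV small RNA-seq experiment
#'
#' A design mirrors the structure the downstream analysis assumes: two
#' genotypes (Q331K, WT) crossed with two timepoints (3m, 6m) and two sexes
#' (F, M), `n_per_cell` replicates per cell (24 samples at the default 3),
#' negative-binomial counts with a strongly skewed library composition, and
#' a genotype effect planted on a chosen feature subset. Timepoint and sex
#' never modulate means, so any apparent effect there is noise.
#'
#' @param n_features number of miRNA features to simulate.
#' @param n_per_cell replicates per genotype x timepoint x sex cell.
#' @param planted `NULL`, or a data frame with columns `mirna` and `log2fc`
#'   giving the signed log2 fold change (Q331K over WT) planted on each named
#'   feature. Feature names follow the generator's `syn-miR-<k>-5p` scheme.
#' @param dispersion negative-binomial dispersion, a single value or one per
#'   feature; `0` gives Poisson counts.
#' @param baseline_log_mean_range range (natural-log scale) of the baseline
#'   relative-abundance weights; the default spans ~3 decades so per-feature
#'   totals spread over roughly 1e3-1e6 at the default depth.
#' @param library_size_range range of per-sample library sizes (reads).
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_design`.
#' @examples
#' d <- synthetic_design(n_features = 50, planted = data.frame(
#'   mirna = "syn-miR-1-5p", log2fc = 2))
#' sim <- simulate_counts(d)
#' sim$counts
#' @export
synthetic_design <- function(n_features = 300L,
                             n_per_cell = 3L,
                             planted = NULL,
                             dispersion = 0.1,
                             baseline_log_mean_range = c(log(5), log(5000)),
                             library_size_range = c(5e5, 2e6),
                             seed = 1L) {
  stopifnot(n_features >= 1L, n_per_cell >= 1L)
  if (any(dispersion < 0)) stop("`dispersion` must be >= 0", call. = FALSE)
  if (!length(dispersion) %in% c(1L, n_features)) {
    stop("`dispersion` must have length 1 or n_features", call. = FALSE)
  }
  stopifnot(
    length(baseline_log_mean_range) == 2L,
    baseline_log_mean_range[1] <= baseline_log_mean_range[2],
    length(library_size_range) == 2L,
    library_size_range[1] > 0,
    library_size_range[1] <= library_size_range[2]
  )
  features <- sprintf("syn-miR-%d-5p", seq_len(n_features))
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!all(c("mirna", "log2fc") %in% names(planted))) {
      stop("`planted` needs columns `mirna` and `log2fc`", call. = FALSE)
    }
    missing_feats <- setdiff(planted$mirna, features)
    if (length(missing_feats) > 0L) {
      stop("planted features outside the feature set: ",
           paste(missing_feats, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(planted$mirna)) {
      stop("duplicated planted feature names", call. = FALSE)
    }
  }
  structure(
    list(
      n_features = as.integer(n_features),
      n_per_cell = as.integer(n_per_cell),
      features = features,
      planted = planted,
      dispersion = dispersion,
      baseline_log_mean_range = baseline_log_mean_range,
      library_size_range = library_size_range,
      seed = as.integer(seed)
    ),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design> %d features, %d samples (2x2x2 x %d), %d planted, seed %d\n",
    x$n_features, 8L * x$n_per_cell, x$n_per_cell,
    if (is.null(x$planted)) 0L else nrow(x$planted), x$seed
  ))
  invisible(x)
}

#' Generate a synthetic mature-miRNA reference
#'
#' Random RNA-alphabet sequences named `syn-miR-<k>-5p`, unique by
#' construction and deterministic for a fixed seed.
#'
#' @param n_features number of sequences.
#' @param length_range inclusive mature-length range; must lie within 18-25 nt.
#' @param seed integer RNG seed.
#' @return A tibble with columns `mirna` and `sequence` (RNA alphabet).
#' @examples
#' simulate_reference(5, seed = 7)
#' @export
simulate_reference <- function(n_features, length_range = c(18L, 25L), seed = 1L) {
  stopifnot(n_features >= 1L, length(length_range) == 2L)
  length_range <- as.integer(length_range)
  if (length_range[1] > length_range[2] ||
      length_range[1] < 18L || length_range[2] > 25L) {
    stop("`length_range` must be ordered and within 18-25 nt", call. = FALSE)
  }
  space <- sum(4^(seq(length_range[1], length_range[2])))
  if (n_features > space) {
    stop("cannot draw ", n_features, " unique sequences from a space of ",
         space, call. = FALSE)
  }
  with_seed(seed, {
    seqs <- character(0)
    tries <- 0L
    len_pool <- seq(length_range[1], length_range[2])
    while (length(seqs) < n_features) {
      need <- n_features - length(seqs)
      lens <- len_pool[sample.int(length(len_pool), need, replace = TRUE)]
      new <- vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
      }, character(1))
      seqs <- unique(c(seqs, new))
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("failed to generate unique sequences", call. = FALSE)
      }
    }
    tibble(
      mirna = sprintf("syn-miR-%d-5p", seq_len(n_features)),
      sequence = seqs[seq_len(n_features)]
    )
  })
}

#' Simulate a raw count matrix with planted genotype effects
#'
#' Counts are drawn feature-by-feature from a negative binomial with mean
#' `library_size * relative_abundance * 2^(sign * log2fc / 2)`, where the
#' sign splits the planted effect symmetrically between genotypes (+fc/2 in
#' Q331K, -fc/2 in WT) so the grand mean is effect-free. Timepoint and sex
#' never enter the mean.
#'
#' @param design a [synthetic_design()].
#' @param compartment compartment label recorded in the sample table.
#' @return A list of class `ev_simulation`: `counts` (raw count tibble),
#'   `samples` (sample metadata with true library sizes) and `truth`
#'   (per-feature true log2 fold change, 0 for non-planted features).
#' @export
simulate_counts <- function(design, compartment = "BDEV") {
  stopifnot(inherits(design, "synthetic_design"))
  n <- design$n_features
  with_seed(design$seed, {
    samples <- tidyr::expand_grid(
      genotype = c("Q331K", "WT"),
      timepoint = c("3m", "6m"),
      sex = c("F", "M"),
      replicate = seq_len(design$n_per_cell)
    )
    samples <- mutate(
      samples,
      sample = sprintf("%s_%02d", compartment, row_number()),
      compartment = compartment,
      library_size = round(runif(
        dplyr::n(),
        design$library_size_range[1],
        design$library_size_range[2]
      ))
    )
    samples <- select(samples, "sample", "genotype", "timepoint", "sex",
                      "compartment", "library_size")

    w <- exp(runif(n, design$baseline_log_mean_range[1],
                   design$baseline_log_mean_range[2]))
    p <- w / sum(w)
    log2fc <- setNames(rep(0, n), design$features)
    if (!is.null(design$planted)) {
      log2fc[design$planted$mirna] <- design$planted$log2fc
    }
    disp <- rep(design$dispersion, length.out = n)

    sign_g <- ifelse(samples$genotype == "Q331K", +0.5, -0.5)
    counts <- matrix(0, nrow = n, ncol = nrow(samples),
                     dimnames = list(design$features, samples$sample))
    for (f in seq_len(n)) {
      mu <- samples$library_size * p[f] * 2^(sign_g * log2fc[f])
      counts[f, ] <- if (disp[f] == 0) {
        rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / disp[f])
      }
    }

    truth <- tibble(mirna = design$features, true_log2fc = unname(log2fc))
    structure(
      list(
        counts = as_count_tbl(counts, units = "raw"),
        samples = samples,
        truth = truth
      ),
      class = "ev_simulation"
    )
  })
}

#' Specify the isomiR profile of simulated reads
#'
#' Each simulated read may carry terminal variants (extra or missing bases at
#' either end, at most 2 per category) and up to 2 internal substitutions,
#' matching the tolerance of the downstream aligner. At each end a read is
#' unmodified with probability `1 - p_end`, otherwise it either gains or
#' loses 1-2 bases (equally likely).
#'
#' @param p_end per-end modification probability.
#' @param p_sub probability that a read carries >= 1 substitution.
#' @param max_add5,max_add3,max_miss5,max_miss3 bounds on terminal variants;
#'   must not exceed 2.
#' @param max_sub bound on substitutions per read; must not exceed 2.
#' @return An object of class `isomir_profile`.
#' @export
isomir_profile <- function(p_end = 0.2, p_sub = 0.05,
                           max_add5 = 2L, max_add3 = 2L,
                           max_miss5 = 2L, max_miss3 = 2L,
                           max_sub = 2L) {
  bounds <- c(max_add5 = max_add5, max_add3 = max_add3,
              max_miss5 = max_miss5, max_miss3 = max_miss3,
              max_sub = max_sub)
  if (any(bounds < 0L) || any(bounds > 2L)) {
    stop("isomiR bounds must lie in 0..2 (terminal variants and substitutions)",
         call. = FALSE)
  }
  stopifnot(p_end >= 0, p_end <= 1, p_sub >= 0, p_sub <= 1)
  structure(
    list(p_end = p_end, p_sub = p_sub,
         max_add5 = as.integer(max_add5), max_add3 = as.integer(max_add3),
         max_miss5 = as.integer(max_miss5), max_miss3 = as.integer(max_miss3),
         max_sub = as.integer(max_sub)),
    class = "isomir_profile"
  )
}

#' Simulate small RNA reads with isomiR variants
#'
#' Draws reads from a mature-miRNA reference, applies terminal variants and
#' internal substitutions per the profile, appends the 3' sequencing adapter
#' and emits DNA-alphabet reads with constant Phred quality. The default
#' adapter is the QIAseq miRNA 3' adapter. Ground truth records every edit
#' so that tests can reconstruct each read from its source.
#'
#' @param reference tibble with columns `mirna`, `sequence` (RNA or DNA).
#' @param n_reads number of reads.
#' @param abundances optional per-feature sampling weights (named or in
#'   reference order); default uniform.
#' @param profile an [isomir_profile()].
#' @param adapter 3' adapter sequence (DNA) appended to every read.
#' @param seed integer RNG seed.
#' @return A list of class `ev_read_sim`: `reads` (tibble `read_id`,
#'   `sequence`, `quality`) and `truth` (per-read source and edits).
#' @export
simulate_reads <- function(reference, n_reads, abundances = NULL,
                           profile = isomir_profile(),
                           adapter = "AACTGTAGGCACCATCAAT",
                           seed = 1L) {
  stopifnot(inherits(profile, "isomir_profile"), n_reads >= 1L)
  if (!nzchar(adapter)) stop("`adapter` must be non-empty", call. = FALSE)
  validate_nucleotides(adapter, arg = "adapter")
  if (grepl("[Uu]", adapter)) stop("`adapter` must be a DNA sequence", call. = FALSE)
  src_seq <- to_dna(toupper(reference$sequence))
  names(src_seq) <- reference$mirna
  if (is.null(abundances)) abundances <- rep(1, length(src_seq))
  if (!is.null(names(abundances))) abundances <- abundances[reference$mirna]
  stopifnot(length(abundances) == length(src_seq), all(abundances >= 0))

  with_seed(seed, {
    idx <- sample.int(length(src_seq), n_reads, replace = TRUE, prob = abundances)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      src <- src_seq[[idx[i]]]
      nsrc <- nchar(src)
      # 5' end: none / add / miss
      e5 <- sample(c("none", "add", "miss"), 1L,
                   prob = c(1 - profile$p_end, profile$p_end / 2, profile$p_end / 2))
      e3 <- sample(c("none", "add", "miss"), 1L,
                   prob = c(1 - profile$p_end, profile$p_end / 2, profile$p_end / 2))
      miss5 <- if (e5 == "miss" && profile$max_miss5 > 0L) sample.int(profile$max_miss5, 1L) else 0L
      miss3 <- if (e3 == "miss" && profile$max_miss3 > 0L) sample.int(profile$max_miss3, 1L) else 0L
      n_add5 <- if (e5 == "add" && profile$max_add5 > 0L) sample.int(profile$max_add5, 1L) else 0L
      n_add3 <- if (e3 == "add" && profile$max_add3 > 0L) sample.int(profile$max_add3, 1L) else 0L
      core <- substr(src, miss5 + 1L, nsrc - miss3)
      # substitutions inside the core only, guaranteed to change the base
      n_sub <- if (profile$max_sub > 0L && runif(1) < profile$p_sub) {
        sample.int(profile$max_sub, 1L)
      } else 0L
      sub_pos <- integer(0); sub_base <- character(0)
      if (n_sub > 0L) {
        sub_pos <- sort(sample.int(nchar(core), min(n_sub, nchar(core))))
        for (pp in sub_pos) {
          old <- substr(core, pp, pp)
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          substr(core, pp, pp) <- new
          sub_base <- c(sub_base, new)
        }
      }
      add5 <- if (n_add5 > 0L) paste(sample(c("A", "C", "G", "T"), n_add5, replace = TRUE), collapse = "") else ""
      add3 <- if (n_add3 > 0L) paste(sample(c("A", "C", "G", "T"), n_add3, replace = TRUE), collapse = "") else ""
      insert <- paste0(add5, core, add3)
      rows[[i]] <- tibble(
        read_id = sprintf("read_%05d", i),
        mirna = names(src_seq)[idx[i]],
        add5 = add5, add3 = add3,
        miss5 = miss5, miss3 = miss3,
        n_sub = length(sub_pos),
        sub_pos = paste(sub_pos, collapse = ","),
        sub_base = paste(sub_base, collapse = ","),
        insert = insert
      )
    }
    truth <- list_rbind(rows)
    reads <- tibble(
      read_id = truth$read_id,
      sequence = paste0(truth$insert, adapter),
      quality = strrep("I", nchar(truth$insert) + nchar(adapter))
    )
    structure(list(reads = reads, truth = truth, adapter = adapter),
              class = "ev_read_sim")
  })
}

#' Reconstruct a simulated read insert from its recorded edits
#'
#' Applies the ground-truth edit description (missing terminal bases,
#' substitutions, added terminal bases) to a source mature sequence;
#' the result must equal the simulated read minus its adapter.
#'
#' @param source_sequence the mature sequence (RNA or DNA).
#' @param truth_row one row of the `truth` table from [simulate_reads()].
#' @return The reconstructed insert (DNA alphabet).
#' @export
apply_read_edits <- function(source_sequence, truth_row) {
  src <- to_dna(toupper(source_sequence))
  core <- substr(src, truth_row$miss5 + 1L, nchar(src) - truth_row$miss3)
  if (nzchar(truth_row$sub_pos)) {
    pos <- as.integer(strsplit(truth_row$sub_pos, ",")[[1]])
    base <- strsplit(truth_row$sub_base, ",")[[1]]
    for (j in seq_along(pos)) substr(core, pos[j], pos[j]) <- base[j]
  }
  paste0(truth_row$add5, core, truth_row$add3)
}
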