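# Independent oracles used across tests. Each is written as a direct,
# unoptimized evaluation of the definition, separate from the package's
# implementation path.

# Exhaustive isomiR aligner: enumerate every (add5, add3, miss5, miss3)
# tuple against every reference, collect all candidates, pick the best by
# (mismatches, total end variants, add5, reference name).
oracle_align <- function(read, reference, max_mm = 2, bound = 2, min_len = 15) {
  read <- chartr("Uu", "Tt", toupper(read))
  if (nchar(read) < min_len) {
    return(list(status = "too_short", mirna = NA_character_))
  }
  cands <- list()
  for (j in seq_len(nrow(reference))) {
    ref <- chartr("Uu", "Tt", toupper(reference$sequence[j]))
    for (add5 in 0:bound) for (add3 in 0:bound) {
      for (miss5 in 0:bound) for (miss3 in 0:bound) {
        core_len <- nchar(ref) - miss5 - miss3
        if (core_len < 1) next
        if (nchar(read) != add5 + core_len + add3) next
        rc <- substr(read, add5 + 1, add5 + core_len)
        mc <- substr(ref, miss5 + 1, nchar(ref) - miss3)
        mm <- sum(strsplit(rc, "")[[1]] != strsplit(mc, "")[[1]])
        if (mm <= max_mm) {
          cands[[length(cands) + 1]] <- data.frame(
            mirna = reference$mirna[j], mm = mm,
            mods = add5 + add3 + miss5 + miss3,
            add5 = add5, add3 = add3, miss5 = miss5, miss3 = miss3
          )
        }
      }
    }
  }
  if (length(cands) == 0) {
    return(list(status = "unaligned", mirna = NA_character_))
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(cands$mm, cands$mods, cands$add5, cands$mirna), ]
  best <- cands[1, ]
  ties <- cands[cands$mm == best$mm & cands$mods == best$mods, ]
  if (length(unique(ties$mirna)) > 1) {
    return(list(status = "ambiguous", mirna = NA_character_))
  }
  list(status = "assigned", mirna = best$mirna, mm = best$mm,
       add5 = best$add5, add3 = best$add3,
       miss5 = best$miss5, miss3 = best$miss3)
}

# Doubly trimmed, inverse-variance-weighted mean of M values, evaluated by
# explicit sorting and index arithmetic.
oracle_tmm_factor <- function(obs, ref, lib_obs, lib_ref,
                              trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep] / lib_obs
  r <- ref[keep] / lib_ref
  M <- log2(o / r)
  A <- 0.5 * log2(o * r)
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
    (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  if (max(abs(M)) < 1e-10) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(M) >= lo_m & rank(M) <= hi_m & rank(A) >= lo_a & rank(A) <= hi_a
  2^(sum((M / w)[sel]) / sum((1 / w)[sel]))
}

# Naive all-windows substring scan for seed sites.
oracle_seed_scan <- function(site, utr) {
  site <- chartr("Uu", "Tt", toupper(site))
  utr <- chartr("Uu", "Tt", toupper(utr))
  n <- nchar(site)
  starts <- integer(0)
  if (nchar(utr) >= n) {
    for (i in seq_len(nchar(utr) - n + 1)) {
      if (substr(utr, i, i + n - 1) == site) starts <- c(starts, i)
    }
  }
  starts
}

# Closed-form pooled two-sample t-test p-value.
oracle_pooled_t_p <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  2 * pt(-abs(t), df = length(a) + length(b) - 2)
}

# Direct evaluation of the BH step-up recursion.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  adj[order(o)]
}

# Random DNA string.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Small labelled experiment used by several weighting tests.
planted_simulation <- function(seed, n_features = 300, n_planted = 10,
                               dispersion = 0.1, n_per_cell = 3) {
  set.seed(seed)
  planted <- data.frame(
    mirna = sprintf("syn-miR-%d-5p", sample(n_features, n_planted)),
    log2fc = sample(c(-1, 1), n_planted, TRUE) * runif(n_planted, 1, 2)
  )
  d <- synthetic_design(n_features, n_per_cell, planted = planted,
                        dispersion = dispersion, seed = seed)
  sim <- simulate_counts(d)
  list(sim = sim, planted = planted)
}

# Mann-Whitney AUC of a score for recovering a logical label.
recovery_auc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
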