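test_that("adapter trimming finds the leftmost tolerant occurrence", {
  adapter <- "TGGAATTCTCGG"
  insert <- "ACGTACGTACGTACGTAC"
  expect_equal(trim_adapter(paste0(insert, adapter), adapter), insert)
  # no adapter: unchanged
  expect_equal(trim_adapter(insert, adapter), insert)
  # read that is adapter alone: empty
  expect_equal(trim_adapter(adapter, adapter), "")
  # partial 3' overlap >= min_overlap is trimmed
  expect_equal(trim_adapter(paste0(insert, substr(adapter, 1, 8)), adapter), insert)
  # 7-base overlap is below min_overlap: untouched
  short <- paste0(insert, substr(adapter, 1, 7))
  expect_equal(trim_adapter(short, adapter), short)
  # one mismatch in a 12-base overlap passes max_error_rate = 0.125
  mm <- adapter; substr(mm, 3, 3) <- "A"
  expect_equal(trim_adapter(paste0(insert, mm), adapter), insert)
  # empty read stays empty
  expect_equal(trim_adapter("", adapter), "")
})

test_that("alignment handles identity, mismatch bounds and end variants", {
  ref <- tibble::tibble(mirna = "m1", sequence = "UGGAGUGUGACAAUGGUGUUUG")
  dna <- chartr("U", "T", ref$sequence)

  hit <- align_reads(dna, ref)
  expect_equal(hit$status, "assigned")
  expect_equal(hit$n_mismatches, 0L)
  expect_equal(unlist(hit[, c("add5", "add3", "miss5", "miss3")],
                      use.names = FALSE), c(0L, 0L, 0L, 0L))

  # 3 internal substitutions exceed the 2-mismatch bound
  r3 <- dna
  substr(r3, 5, 5) <- "C"; substr(r3, 10, 10) <- "C"; substr(r3, 15, 15) <- "C"
  expect_equal(align_reads(r3, ref)$status, "unaligned")

  # missing first 2 bases, 1 extra 3' base, 1 internal substitution
  r <- paste0(substr(dna, 3, nchar(dna)), "A")
  substr(r, 8, 8) <- if (substr(r, 8, 8) == "C") "G" else "C"
  out <- align_reads(r, ref)
  expect_equal(out$status, "assigned")
  expect_equal(out$n_mismatches, 1L)
  expect_equal(unlist(out[, c("add5", "add3", "miss5", "miss3")],
                      use.names = FALSE), c(0L, 1L, 2L, 0L))
  orc <- oracle_align(r, ref)
  expect_equal(orc[c("add5", "add3", "miss5", "miss3")],
               list(add5 = 0, add3 = 1, miss5 = 2, miss3 = 0))

  # too-short reads are flagged, not aligned
  expect_equal(align_reads("ACGTACGT", ref)$status, "too_short")
})

test_that("aligner equals the exhaustive oracle on random cases", {
  set.seed(101)
  ref <- simulate_reference(5, seed = 77)
  policy <- alignment_policy()
  for (case in 1:200) {
    read <- random_dna(1, sample(15:30, 1))
    # half the cases: perturbed real reference, so assignments are common
    if (case %% 2 == 0) {
      j <- sample(5, 1)
      src <- chartr("U", "T", ref$sequence[j])
      read <- substr(src, sample(1:3, 1), nchar(src) - sample(0:2, 1))
      if (runif(1) < 0.5) {
        p <- sample(nchar(read), 1)
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (nchar(read) < 15) read <- paste0(read, "AA")
    }
    got <- align_reads(read, ref, policy)
    want <- oracle_align(read, ref)
    expect_equal(got$status, want$status, info = paste("case", case, read))
    if (want$status == "assigned") {
      expect_equal(got$mirna, want$mirna, info = read)
      expect_equal(got$n_mismatches, want$mm, info = read)
      expect_equal(got$add5 + got$add3 + got$miss5 + got$miss3,
                   want$add5 + want$add3 + want$miss5 + want$miss3, info = read)
    }
  }
})

test_that("tightening any policy bound never rescues an unaligned read", {
  set.seed(55)
  ref <- simulate_reference(8, seed = 12)
  reads <- random_dna(150, 22)
  loose <- align_reads(reads, ref, alignment_policy())
  tighter <- list(
    alignment_policy(max_mismatches = 1),
    alignment_policy(max_add5 = 0, max_add3 = 0),
    alignment_policy(max_miss5 = 1, max_miss3 = 1)
  )
  for (pol in tighter) {
    tight <- align_reads(reads, ref, pol)
    gained <- tight$status == "assigned" & loose$status == "unaligned"
    expect_false(any(gained))
  }
})

test_that("assignments are invariant to U/T representation", {
  ref <- simulate_reference(6, seed = 31)
  ref_dna <- ref; ref_dna$sequence <- chartr("U", "T", ref$sequence)
  reads <- substr(chartr("U", "T", ref$sequence), 2, 20)
  a <- align_reads(reads, ref)
  b <- align_reads(chartr("T", "U", reads), ref_dna)
  expect_equal(a[, -1], b[, -1])
})

test_that("ambiguous reads are discarded or assigned first-by-name", {
  ref <- tibble::tibble(
    mirna = c("m-b", "m-a"),
    sequence = c("ACGUACGUACGUACGUACGU", "ACGUACGUACGUACGUACGU")
  )
  read <- "ACGTACGTACGTACGTACGT"
  expect_equal(align_reads(read, ref)$status, "ambiguous")
  first <- align_reads(read, ref, alignment_policy(ambiguous = "first_by_name"))
  expect_equal(first$status, "assigned")
  expect_equal(first$mirna, "m-a")
})

test_that("quantification round-trips the generator's ground truth", {
  ref <- simulate_reference(15, seed = 8)

  # zero-edit reads: counts equal the true source tallies exactly
  rs0 <- simulate_reads(ref, 300, profile = isomir_profile(p_end = 0, p_sub = 0),
                        seed = 14)
  q0 <- quantify_reads(list(s1 = rs0$reads), ref, adapter = rs0$adapter)
  truth_tab <- table(factor(rs0$truth$mirna, levels = sort(ref$mirna)))
  expect_equal(unname(as.matrix(q0$counts[, -1])[, 1]), as.numeric(truth_tab))
  expect_equal(q0$summary$assigned, 300)
  # column sums equal assigned-read counts
  expect_equal(sum(q0$counts$s1), q0$summary$assigned)

  # isomiR reads within bounds: every read recovered as its true source
  rs <- simulate_reads(ref, 500, profile = isomir_profile(p_end = 0.4, p_sub = 0.2),
                       seed = 15)
  q <- quantify_reads(list(s1 = rs$reads), ref, adapter = rs$adapter)
  asn <- q$assignments$s1
  expect_true(all(asn$status == "assigned"))
  expect_equal(asn$mirna, rs$truth$mirna)
})

test_that("a sample with zero assigned reads is kept as a flagged zero column", {
  ref <- simulate_reference(5, seed = 2)
  junk <- tibble::tibble(read_id = "r1", sequence = strrep("A", 30),
                         quality = strrep("I", 30))
  expect_warning(
    q <- quantify_reads(list(bad = junk), ref),
    "zero assigned reads"
  )
  expect_true(all(q$counts$bad == 0))
})
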