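---
title: "Methods: EV miRNA panel discovery with evmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV miRNA panel discovery with evmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmir)
```

evmir re-implements, as tested reusable functions, the computational path
from small RNA-seq reads of extracellular vesicles (EVs) to a pair of
compartment-specific miRNA biomarker panels and their intersection. The
motivating comparison is TDP-43\*Q331K (an ALS-associated TDP-43 variant)
against TDP-43\*WT transgenic mice, profiled in brain-derived EVs (BDEVs)
and serum EVs from the same animals. This vignette documents the models,
the tunable parameters and their defaults, the numerical conventions, and
the design decisions taken where the procedure was genuinely open.

## The synthetic experiment

No raw sequencing data are available for this design, so the package ships
a generator (`synthetic_design()`, `simulate_counts()`) whose defaults are
the study's conditions:

* **Design**: 2 genotypes (Q331K, WT) × 2 timepoints (3m, 6m) × 2 sexes
  (F, M) × 3 replicates = 24 samples per compartment.
* **Counts**: negative binomial per feature, mean = library size ×
  relative abundance × genotype multiplier, dispersion 0.1 by default.
  The NB is our choice — the study does not state a count model — as the
  standard overdispersed model for RNA-seq that also matches the
  heavy-tailed per-miRNA totals of the published tables.
* **Composition**: baseline relative-abundance weights are log-uniform
  over `exp([log 5, log 5000])`, which at 0.5–2 M reads/sample spreads
  per-feature totals over roughly 10^3–10^6, the range of the published
  per-miRNA totals. Feature count defaults to 300, a typical number of
  detectably expressed miRNAs in such libraries. Per-sample depth
  (0.5–2 M) is a configurable default; the study reports no depths.
* **Effects**: a planted log2 fold change applies only to genotype, split
  symmetrically (+fc/2 to Q331K, −fc/2 to WT) so the grand mean is
  effect-free and library composition stays comparable. Timepoint and sex
  never modulate means — the generator encodes the study's finding that
  they had no effect as a ground-truth property the pipeline must confirm,
  not discover. The default planted effect profile
  (`default_planted()`) reuses the published panels' signed log2 ratios
  (24 effects for BDEV, 7 for serum, |log2 FC| 0.58–2.63, the first two
  features shared), so a default pipeline run reproduces the structure of
  the study: two overlapping panels.
* **Reads**: `simulate_reads()` emits DNA-alphabet reads (mature
  references are RNA; the aligner treats U≡T) with a 3′ QIAseq-style
  adapter, constant Phred quality (quality is never used downstream), and
  isomiR edits bounded at 2 bases per end and 2 substitutions — exactly
  the aligner's tolerance. Ground truth records every edit; a test
  reconstructs each read from its recorded edits.

What the generator does **not** emulate: UMI structure (reads are counted,
not UMI-collapsed), position-dependent sequencing error, adapter dimers,
quality-score realism, and between-feature count correlation. Passing
tests on this generator therefore demonstrate correctness of the
*computational conventions* and sensible statistical behaviour under the
stated design, not performance on real libraries.

## Quantification

`trim_adapter()` removes everything from the leftmost adapter occurrence;
an occurrence is a ≥ 8-base overlap (or the full adapter) with mismatch
fraction ≤ 0.125. `align_reads()` then decomposes a read as
`add5 + core + add3` against each mature sequence minus `miss5`/`miss3`
terminal bases, with all four end variants ≤ 2 and Hamming mismatches in
the core ≤ 2 (`alignment_policy()`).

Decisions where the original tooling is under-specified:

* **Extra terminal bases** are unconstrained and never counted as
  mismatches. The original workflow templates them against the genome; we
  operate genome-free, so this is the conservative reinterpretation, and
  it is what the exhaustive-search oracle checks.
* **Best candidate** minimizes (mismatches, total end variants), then
  smaller `add5` — a canonical-form preference that makes assignment
  deterministic.
* **Multi-mapping** reads (ties across references) are discarded by
  default (`ambiguous = "discard"`), avoiding double counting;
  `"first_by_name"` is the deterministic alternative.
* **`min_length = 15`**: the shortest mature miRNAs (18 nt) minus the
  allowed missing bases; shorter trimmed reads are `too_short`.

`quantify_reads()` tallies assigned reads per (miRNA, sample); a sample
with zero assigned reads is kept as an all-zero column and flagged.

## Normalization and sample QC

`cpm_normalize()` is counts/library-size × 10^6. `tmm_normalize()`
implements the trimmed mean of M-values on library-scaled proportions of
features expressed in both samples: per-feature log2 ratios (M) doubly
trimmed (30% on M, 5% on A — the method's published defaults; the study
cites the method without parameters), averaged with
inverse-asymptotic-variance weights, factor = 2^(weighted mean), factors
rescaled to geometric mean 1. The reference sample is the one whose upper
quartile of scaled counts is closest to the mean upper quartile. An
independent hand-coded evaluation and edgeR's implementation both serve as
cross-checks in the test suite.

`pca_qc()` decomposes feature-centered log2(CPM + 0.5) by SVD (log2 with a
0.5 offset is the standard variance-taming transform for counts; features
are centered, not scaled). A sample is flagged when its distance from the
score-space centroid (first `k = 2` components) exceeds the median
distance by more than `flag_sd = 3` robust SDs (MAD × 1.4826). The study
removed one Q331K sample without stating a rule; this robust-z rule is our
declared, testable stand-in. We state it as a z-score on distances rather
than a raw MAD multiple because distances concentrate away from zero: a
raw multiple would flag every sample in exactly the geometry an outlier
rule must handle (many near-identical samples plus one far point). On null
data the rule flags ~1% of samples.

## Attribute weighting

`weigh_features()` scores every feature against a class label with seven
models. The categorical five (information gain, gain ratio, chi-squared,
Gini impurity decrease, symmetric uncertainty — entropies in bits) and
one-rule operate on a discretized feature: equal-frequency quantile bins,
4 by default, duplicate cut points merged (`discretize()`); the
discretization scheme is ours — the original platform's internals are not
stated — chosen for determinism and scale invariance. One-rule's weight is
majority-class-per-bin accuracy minus the majority-class baseline, floored
at 0, so an uninformative feature scores exactly 0. Relief is ReliefF on
continuous features: all instances visited, k = 10 nearest hits/misses by
Euclidean distance on range-scaled features, prior-weighted across
classes.

Each model's weights are rescaled to [0, 1] with raw weight 0 anchored at
normalized 0 ("non-important") and the column maximum at 1; negative
Relief weights floor at 0. We anchor at zero rather than at the column
minimum because the models are (Relief aside) non-negative with 0 meaning
statistical independence from the label; anchoring at the minimum would
let an irrelevant feature's score depend on which other features happen to
be in the table. The ensemble score is the sum over the seven normalized
columns (range [0, 7]); features are ranked by it, ties broken by name.
"Highest weights" is exposed as a configurable top-k (default 30) with the
full ranking always returned.

Weighting runs on log2(CPM + 0.5) by default (`weigh_counts()`); whether
the original analysis weighted raw counts, CPM or log-CPM is not stated,
and the equal-frequency bins make the categorical models invariant to any
monotone choice.

`confounder_scan()` repeats the ensemble against genotype, timepoint and
sex. On data with genotype-only effects, the planted features rank *at or
below* chance under timepoint and sex — the genotype effect inflates
within-class variance, which suppresses their weights against orthogonal
labels — so the nullity check is one-sided: no evidence that planted
features rank better than uniform.

## Differential expression and panels

Features with mean CPM ≥ 5 across all samples (inclusive) are tested:
one-way fixed-effects ANOVA (pooled variance; equivalent to the two-sided
pooled t for two groups) on log2(CPM + 0.5), genotypes pooled across
timepoints. `fdr_step_up()` is Benjamini–Hochberg. Effect sizes are ratios
of within-group geometric means computed with a 0.5 pseudocount inside the
log (the pseudocount is our choice; zeros require one), with
log2(ratio) and the signed fold change FC = r if r ≥ 1 else −1/r.

The panel gate (`select_panel()`) is **raw p < 0.05 and |FC| ≥ 1.5,
inclusive**. Two deliberate conventions:

* The gate uses the raw p-value, not the FDR column: the published panels
  contain FDR values up to 0.67, so they cannot have been FDR-gated; the
  FDR column is reported for transparency.
* The fold-change comparison is inclusive (≥ 1.5): the published serum
  panel contains a row at exactly FC −1.50, which a strict gate would
  drop. A `inclusive = FALSE` flag gives the strict variant.

`intersect_panels()` matches names by exact string equality after
whitespace trimming — `-486a` and `-486b` are distinct features. (The
source study's own text and tables disagree on whether the common serum
member is miR-486a-5p or miR-486b-5p; the bundled tables' name sets
support 486b, and we follow the tables without guessing intent.)

## Seed-site scanning

`complement()`/`reverse_complement()` are Watson–Crick with U/T
interchangeable on input and the output alphabet following the input. The
seed is positions 2–8 of the mature sequence, 5′→3′; a site is an exact
occurrence of the seed's reverse complement on the UTR plus strand, all
overlapping occurrences reported with 1-based inclusive coordinates. Only
exact 7-mers are called — no 7mer-A1/8mer subtypes and no conservation
scoring, which belong to database-backed target predictors outside this
package's scope. Note that published "region" strings for miRNAs are often
printed 3′→5′ (e.g. UGUGAGG for miR-122-5p, whose 5′→3′ seed is GGAGUGU);
all evmir functions operate on 5′→3′ strings.

## Numerical conventions and degenerate inputs

* Geometric means use pseudocount 0.5 under the log, subtracted back out
  in summaries (`summarize_features()`), kept inside the ratio in
  `effect_stats()`.
* Zero within-group variance in both groups: p = 1 when means agree, the
  smallest positive double (with a warning) when they differ.
* Constant features discretize to a single bin and receive weight 0 in
  every model; a constant column of weights normalizes to all 0.
* `alpha = 0` is accepted by `select_panel()` and yields an empty panel.
* All generators consume one integer seed each and are bit-reproducible;
  `run_pipeline()` derives per-stage seeds from the master seed and its
  resolved-config snapshot reproduces a run byte-for-byte.

## Problem sizes used in validation

The test and acceptance suites run the study-scale design (24 samples,
300 features, NB dispersion 0.1, 10 planted effects with |log2 FC| in
[1, 2]) over 20 seeds for ensemble recovery (mean AUC ≈ 1.0), confounder
nullity and planted-effect recovery, and 20 × 1000 null features for
p-value calibration (pooled rejection rate 0.050). Planted-effect recovery
is assessed as the per-seed mean bias of the estimated log2 ratio: the
geometric-mean estimator carries an O(1/μ) offset at low counts (visible
as ≈ −0.15 worst-case mean bias at n = 12/group), which shrinks with
abundance and replication; per-feature sampling noise at n = 12 exceeds
any such bias. Aligner correctness is established by equivalence with an
exhaustive search over all end-variant tuples on 1000 random
read/reference pairs.

## Known limitations

* Read counting is not UMI-aware; with the original UMI-tagged libraries,
  counts here would be inflated by PCR duplicates.
* The variance model is ordinary ANOVA, not moderated (empirical Bayes);
  at n = 11–12 per group this is what the original analysis used, but
  limma/DESeq2-style moderation would be more powerful at smaller n.
* The PCA outlier rule is a declared stand-in for an unstated manual QC
  decision.
* Seed scanning is a first-principles 7-mer scan, not a conserved-site
  target database; it reproduces printed complementarity relationships,
  not curated target gene lists.
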