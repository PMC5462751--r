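---
title: "Imbalance-aware variant scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware variant scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`smurfrank` scores variants with a hyper-ensemble: the benign background
`N` is split into `n` disjoint partitions; each partition is combined with
all positives `P`, `f` SMOTE synthetics per positive, and an undersample
of `n_ex = m (f + 1) |P|` negatives; one probability random forest is
trained per partition; and the final score of a variant is the mean of the
`n` per-forest probabilities of deleteriousness, so it always lies in
[0, 1].

The approach assumes that

* the positive class, however small, occupies a coherent region of
  feature space, so that linear interpolation between a positive and one
  of its `k` nearest positive neighbours (Euclidean metric) produces
  plausible new positives. SMOTE is harmful when positives are isolated
  noise points;
* negatives are abundant and individually expendable: each forest sees
  only `n_ex` of them, and coverage of the background comes from the
  union over partitions, not from any single training set;
* base learners benefit from diversity. Synthetics are regenerated
  independently for every partition, so no two forests train on identical
  data even for the shared positives.

No calibration of the averaged score to a probability is attempted: the
output is a ranking score.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n` | 10 | negative partitions = base forests. More partitions raise background coverage at constant per-forest cost; at mild imbalance large `n` starves each partition of negatives (they are then used whole, with a warning). |
| `f` | 2 | SMOTE synthetics per positive (`|P_S| = f |P|`). |
| `m` | 3 | negatives per positive-plus-synthetic in each training set; `m = 1` is exactly balanced, `m = 3` exploits three times more background per forest. |
| `k` | 5 | SMOTE neighbour count; clamped to `|P| − 1` for tiny positive sets. |
| `ntree` | 10 | trees per base forest; the ensemble's effective tree count is `n * ntree`. |
| `mtry` | `ceiling(sqrt(d))` | features tried per split, the random-forest convention. |
| `seed` | — | master seed; per-partition sub-seeds for SMOTE, undersampling and tree growth are derived from it, so serial and parallel execution orders give identical models. |

Trees are grown to purity (`min.node.size = 1`), the classification
random-forest convention; a forest's probability is then its tree-vote
fraction. Smoothed leaves would blur exactly the small disjunctive
positive regions the method is designed to capture.

## Genomics-aware cross-validation

Variants that are genomically close share regulatory context; row-wise
random folds therefore leak location-linked signal. Three fold builders
keep genomic units atomic:

* **Cytogenetic bands** (`cytoband_folds`): bands holding positives are
  assigned greedily — descending positive count, each to the currently
  lightest fold — which balances per-fold positive totals to within the
  largest band count; positive-free bands are placed uniformly at random;
  negatives inherit their band's fold. Only positives are balanced;
  negative counts per fold are left to fall where the bands put them.
* **Merged windows** (`matched_negative_folds`, window mode): a closed
  window of ±`window` bp around every positive, overlapping windows on a
  chromosome merged by a sort-and-sweep union; each merged window is one
  fold, and only negatives inside some window are retained. Because
  overlapping windows merge, a negative can never be within range of
  positives in two different folds, which settles the tie question by
  construction.
* **TADs** (TAD mode): each TAD containing a positive is a fold;
  negatives in positive-free TADs or outside all TADs are dropped; a
  positive outside every TAD is retained as a singleton fold with a
  warning. Interval tables are BED-style 0-based half-open; variant
  positions are 1-based points.

`smurf_cv` refits the whole pipeline per fold — SMOTE runs only on
training-fold positives, so synthetics derived from held-out positives
cannot leak — and returns pooled out-of-fold scores (not per-fold
averages), which is what the matched-negative designs require: each
positive is ranked against its own matched negatives. Per-fold training
and test row indices are recorded, and `cv_audit` verifies after the fact
that no variant was scored by a model that saw it.

The progressive subsampler walks the position-sorted negatives and keeps
every `s`-th one (`s = floor(|N| / target)`), shrinking density while
preserving genomic span; with positives fixed it generates the 1:1, 1:10,
1:100, 1:1000 imbalance series.

## Metrics

* **AUPRC** is non-interpolated average precision — the mean of precision
  at each positive's rank. Linear interpolation of the PR curve
  overestimates the area, so AP is used and stated here because different
  conventions differ materially at heavy imbalance.
* **AUROC** is computed exactly as the Mann–Whitney statistic with half
  credit for ties (via midranks), not by trapezoid.
* Ranking ties are broken by input order (stable sort). For model
  comparisons on coarse scores this makes tie order matter; benchmarks in
  the tests shuffle row order first so ties are class-unbiased.
* F-score is F1. At thresholds where nothing is predicted positive,
  precision is undefined; it is reported as 1.0 and flagged in the
  `degenerate` column rather than silently dropped.
* Sensitivity-vs-quantile reports the fraction of all positives among the
  top `ceiling(q * T)` ranked variants — the "how far down the list must I
  read" view that matters in prioritisation practice.

## Feature transforms

`diff_logfold` uses natural logarithms (the base only rescales a feature
and is irrelevant after standardization) and clips probabilities to
`[1e-6, 1 − 1e-6]` so logits stay finite at saturated predictions. Both
summaries are invariant to swapping the alleles and to the complement
transform `p -> 1 − p`. Column order in the assembled matrix is fixed and
documented — all `diff_*`, then all `logfold_*`, then conservation
columns — so serialised matrices reproduce byte-for-byte.
`standardize` scales to zero mean and unit *population* variance, maps
constant columns to zero with recorded scale 1, and returns its
parameters so the same transform can be applied to new variants; fitting
on all data (the default analysis choice here) or on training folds only
is the caller's decision.

## The synthetic-data generator

`simulate_variants` emulates the *structure* of the real task: a tiny
positive class against a large Gaussian background, genomic coordinates
spread over `n_chrom = 5` synthetic chromosomes of 120 Mb with
`bands_per_chrom = 8` equal-width bands. Positives come from
`n_clusters_pos = 3` sub-clusters whose centroids sit at distance
`separation` (default 2.5, in within-class SD units) from the background
centroid. Centroids are axis-aligned — cluster `j` shifts feature `j` —
because annotation data behaves this way: deleterious variants deviate
strongly in a few features, not diffusely in all of them, and a diffuse
shift is nearly invisible to axis-parallel tree splits at realistic
positive counts. Sub-clusters make SMOTE's neighbour locality
consequential: interpolation within a cluster stays on-manifold, while
cross-cluster interpolation can stray into the background — a real SMOTE
failure mode the tests deliberately leave reachable.

What the generator does **not** emulate: feature correlation structure,
heavy-tailed or discrete annotations, linkage between genomic position
and feature values, and the curation biases of real positive sets.
Passing tests therefore demonstrate algorithmic correctness and
qualitative behaviour under imbalance, not expected performance on real
variants. `simulate_chromatin_pairs` likewise emulates only the shape of
paired allele probabilities (Beta baseline, logit-scale noise, a logit
shift on a fraction of features in positives).

## Numerical and degenerate-input choices

* SMOTE neighbour ties at equal distance break by ascending row index;
  `lambda` is drawn from the closed interval [0, 1], so exact duplicates
  of a positive or its neighbour are possible and are kept.
* A single positive cannot be interpolated: it is duplicated `f` times
  with a warning, preserving the `f |P|` cardinality contract.
* A partition smaller than `n_ex` is used whole, with a warning —
  sampling with replacement would bias trees towards duplicated
  negatives.
* Fold construction fails loudly when a fold would have zero training
  positives; band assignment warns when positive-bearing bands are fewer
  than folds.
* All randomness flows through explicit seeds; functions restore the
  caller's RNG state.

## Problem sizes in the test suite

The suites run at desk scale on one CPU: SMOTE geometry over 200 random
positive sets (`|P| <= 50`, `d <= 10`); metric oracles over instances of
at most 12 variants (exhaustive pair counting stays trivial); benchmark
runs with 40–50 positives against up to 40,000 negatives, five-fold
cross-validation, and ten replicate seeds for the imbalance sweep. The
full suite completes in a couple of minutes; `scripts/acceptance.R` in
under a minute.

## Known limitations

* On overlapping Gaussian mixtures at these scales, the hyper-ensemble's
  advantage shows in the global ranking (cross-validated AUROC ≈ 0.86–0.91
  versus ≈ 0.59–0.73 for a single raw forest at 1:100–1:1000 in the
  acceptance sweep), but a fully grown forest trained on the raw
  imbalanced data keeps better *top-of-ranking* precision: trained at the
  true prior it scores almost nothing as positive, and its few high
  scores are nearly pure, while the balanced training sets score the
  whole class-overlap region confidently positive. The sweep in
  `scripts/acceptance.R` computes both AUPRC series so the effect can be
  inspected directly. Against strongly imbalance-sensitive learners
  (e.g. a plain linear SVM) the hyper-ensemble's AUPRC advantage is the
  expected outcome; against tree ensembles on heavily overlapping classes
  it is not guaranteed.
* The averaged score is not a calibrated probability.
* Base learners are limited to probability forests via `ranger`; the
  pluggable-classifier generalisation is out of scope.
* Window/TAD fold construction assumes point variants (SNVs); structural
  variants spanning unit boundaries are not handled.
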