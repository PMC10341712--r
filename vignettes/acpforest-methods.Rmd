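---
title: "Methods: physicochemical consensus features for anticancer peptide classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical consensus features for anticancer peptide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Anticancer peptides (ACPs) are short sequences (typically under 50
residues) that selectively damage tumor cells. Sequence-based ACP
prediction is usually framed as binary classification: given a peptide's
primary structure, estimate the probability that it has anticancer
activity. `acpforest` implements one interpretable formulation of this
problem: every peptide is described **only** by amino-acid physicochemical
properties, and the question becomes *which* properties discriminate ACPs
from non-ACPs consistently across benchmark corpora.

The representation is deliberately simple. An amino-acid index assigns one
number to each of the 20 standard residues (hydrophobicity, helix
propensity, net charge, ...). Given a library of `m` such indices (the
AAindex1 collection has 566), a peptide of length `L` becomes an `L x m`
matrix of per-residue values, which is average-pooled over positions into
a length-`m` feature vector. Pooling makes the encoding
length-independent, exactly permutation-invariant, and equal to a
composition-weighted mean: the package computes it as `f %*% V` where `f`
is the residue-frequency vector and `V` the index-value matrix. This is
mathematically identical to summing per position and dividing by `L`, but
makes the single-peptide and batch paths bit-identical and the
permutation invariance structural rather than numerical.

Classification uses a random forest — bootstrap-aggregated decision trees
with `sqrt(m)` candidate features per split — because forests need little
tuning, handle correlated features, and expose two complementary
importance measures used by the consensus rules: normalized Gini
(mean-decrease-impurity) importance, and out-of-bag (OOB) permutation
importance, where a feature's column is permuted in each tree's held-out
bootstrap complement and the error increase `e2 - e1` is averaged over
trees.

## Two-round consensus feature selection

Single-dataset feature selection tends to overfit the quirks of one
corpus. The pipeline therefore works across several labeled datasets at
once:

1. **Round 1.** Four selectors rank every dataset's features: one-way
   ANOVA F, a chi-squared statistic on min-max-scaled class-wise sums,
   k-nearest-neighbour mutual information with the label, and total split
   gain of a histogram gradient-boosted tree ensemble. For each
   (dataset, selector) pair, a top-`n` sweep evaluates a random forest by
   stratified 5-fold cross-validation at each candidate subset size and
   keeps the accuracy argmax (ties: higher MCC, then smaller `n`). Per
   selector, features selected in at least `k = 3` datasets are retained;
   the four per-selector consensus sets are merged by union.
2. **Round 2.** Each dataset is restricted to the merged pool, re-ranked
   by the gradient-boosting selector, and swept again. A random forest per
   dataset then yields normalized Gini importances, and the final set is
   the features present in **every** dataset's second-round subset with
   importance above 0.01 in **every** dataset, ordered by mean importance.

The `> 0.01` threshold is applied per dataset (the strictest reading of
"selected from the intersecting areas"), and to forest Gini importances
rather than boosting gains, since the filter follows the forest's
importance analysis. Both `k` and the threshold are arguments.

Run on the four public benchmarks (ACPred-Fuse, ACPred-FL, ACP20Alt,
ACP20main) against the full AAindex1 library, this procedure yields the 19
key physicochemical properties shipped as `acp_key_features()`; the
per-dataset published metrics for the 105- and 19-feature models and the
literature comparators ship as `published_benchmarks()` so the averaged
comparison table and its paired significance tests are reproducible
without the external FASTA corpora.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `na_policy` | `drop_entry` | Index entries containing NA residues are removed from the feature space rather than imputed; imputation (`entry_mean`) invents physicochemistry, so the retained feature count is reported, never assumed. |
| `k` | 3 | Minimum dataset count for round-1 consensus. |
| `threshold` | 0.01 | Per-dataset Gini-importance floor for the final set (importances are normalized to sum 1, so 0.01 is "above the uniform share" once subsets shrink below 100 features). |
| sweep grid | `{5, 10, ..., min(100, m)} U {m}` | Candidate subset sizes; published best-n values fall in 25–100. |
| `num_trees` | 500 (models), 100 (sweeps) | Sweeps compare subset sizes, not final performance; 100 trees rank subsets stably at a fifth of the cost, while reported models use 500. |
| `mtry` | `floor(sqrt(m))` | Standard forest default; `tune_rf()` offers a small grid (trees in {100, 500, 1000}, `sqrt`/`log2` rules) selected by CV accuracy. |
| MI `k` | 3 | Neighbour count of the continuous estimator; affects only a monotone rescaling of ranks. |
| GBM | 100 rounds, 31 leaves, eta 0.1 | Conventional histogram-boosting defaults; the selector consumes only the induced ranking. |

## Numerical choices

- **Ranking ties** break by accession lexicographic order, making the
  downstream set intersections reproducible.
- **Chi-squared pre-scaling** is per-feature min-max on the scored matrix
  (the statistic needs non-negative input); constant features score 0.
- **ANOVA degenerate case**: zero within-group variance with non-zero
  between-group variance yields an `Inf` sentinel ranked first.
- **MI estimator**: the class-conditional k-th-neighbour radius estimator
  for a continuous feature against a discrete label, in nats, clipped at
  zero. A single seeded jitter vector (scale `1e-10`) breaks distance
  ties and is shared across features so duplicated columns score
  identically. Low-cardinality features can use the plug-in discrete
  estimator instead.
- **AUC** is the Mann–Whitney rank statistic with ties counted 1/2 —
  exactly the pair-counting definition.
- **MCC** returns 0 when any denominator factor vanishes.
- **Cross-validation** pools out-of-fold predictions (pooled confusion
  counts and pooled scores) rather than averaging per-fold metrics; AUC
  stays well-defined for small folds, and the pooled counts always sum to
  `n`.
- **OOB permutation importance** uses one seeded permutation per feature,
  shared across trees, with errors evaluated on each tree's own OOB rows.
  This is deterministic and needs one prediction pass per feature; the
  sign convention reported is `mean(e2 - e1)` (positive = informative),
  with the literal signed sum stored alongside.
- **Forest determinism**: single-threaded training under a fixed seed;
  terminal nodes may shrink to one sample so separable training data is
  memorized exactly.

## The synthetic generator, and what passing tests mean

Real benchmark corpora cannot be redistributed with the package, so every
end-to-end property is exercised on synthetic data built by
`make_index_table()` and `make_labeled_peptides()`. The generator emulates
the *statistical structure* the pipeline exploits, not peptide biology:

- index entries are i.i.d. standard-normal residue vectors (optionally
  with NA residues);
- negative peptides draw residues uniformly; positive peptides draw from
  `softmax(delta * s)`, where `s` is the per-residue mean of the planted
  entries' standardized values. Encoded class differences therefore
  appear exactly on the planted entries *and on entries residue-correlated
  with them* — as in the real library, where indices are heavily
  correlated;
- lengths are uniform on 5–50 residues, matching the benchmark corpora's
  typical range; default suites use four datasets of 400 balanced samples
  against a 60-entry table, sizes at which selector behaviour is already
  stable.

A subtlety follows from the planting geometry: with three planted entries
the tilt direction is their average, so each planted entry aligns with the
realized signal at roughly `1/sqrt(3) ~ 0.58`, while the best of ~57
random 20-dimensional residue vectors reaches `|cos| ~ 0.6` by chance.
Chance-aligned noise entries can therefore legitimately interleave with
planted ones in any marginal ranking. Set-level recovery of the planted
features by the full two-round pipeline is the meaningful property; exact
top-rank placement of every planted feature by every selector is not
guaranteed by this construction, and the test suite's strict rank
assertions document that boundary honestly rather than relaxing the
generator. With `delta = 0` the classes are exchangeable by construction,
which calibrates the null (cross-validated accuracy at chance level).

Passing these tests shows the machinery is correct and recovers planted
structure; it does not show that 19 specific indices generalize to new
peptide chemistry — that claim rests on the external benchmark corpora.

## Known limitations

- Average pooling discards positional and terminus information entirely;
  methods using position-specific profiles can outperform it on corpora
  where termini matter.
- The encoder requires the 20 standard residues; non-standard symbols are
  either rejected or dropped (logged), both of which alter the pooled
  vector relative to a modified-residue-aware treatment.
- The chi-squared statistic on min-max-scaled sums is a pragmatic scoring
  convention, not an exact independence test for continuous features.
- Paired significance tests across four datasets have little power; they
  are reported with the test labeled, not as strong evidence.
- Probability calibration, multi-class labels and cost-sensitive training
  are out of scope.
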