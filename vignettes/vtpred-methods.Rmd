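---
title: "Identifying vesicular transport proteins from PSSM profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying vesicular transport proteins from PSSM profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtpred)
```

## The problem

Vesicular transport proteins mediate the membrane-bounded movement of
macromolecules between cellular compartments; their malfunction underlies
several human diseases, and recognising them from sequence alone is far
cheaper than experimental dissection. `vtpred` frames the task as binary
classification of a protein's *evolutionary profile*: the position-specific
scoring matrix (PSSM) produced by iterative PSI-BLAST search, an L x 20
matrix `P` whose entry `P[i, j]` scores how readily position `i` of the
query mutates into amino-acid type `j`. The profile carries conservation
signal that the raw sequence does not, and all features in this package
are functions of it.

The pipeline is: encode each profile into a fixed-length feature vector,
clean the class imbalance on the training side only, rank and prune
features, and train a gradient-boosted tree classifier, evaluating with a
confusion-matrix metric suite under stratified cross-validation and on a
held-out test table.

## Profile normalization

Raw PSSM entries are BLOSUM-scaled integer log-odds, typically in
[-10, 13], and can be negative or sum to zero along a row. The transition
probability composition multiplies consecutive-row entries and divides by
their sums, which is ill-defined on such values, so every encoder consumes
profiles squashed elementwise by the logistic function
`1 / (1 + exp(-x))`. This choice is the package's own: it is monotone (so
per-row argmaxes, and hence the consensus sequence, are unchanged), maps
into (0, 1) (so transition products are positive and the normalized
row sums cannot vanish), and preserves the relative ordering that the
lag-difference encoders measure. `normalize_pssm()` refuses to run twice
on the same profile, since double squashing silently compresses all
contrast toward 0.5.

Column order is fixed to the PSI-BLAST output order
`A R N D C Q E G H I L K M F P S T W V Y`; every feature name indexes
against it. Sequences containing X/B/Z/U are rejected by default; a
permissive flag maps them to X.

## Feature encoders

**AATP (420 features).** The amino-acid composition block is the
per-column profile mean, `x_j = (1/L) sum_i P[i, j]` (20 values). The
transition probability composition forms
`N[i, j] = sum_k P[k, i] * P[k+1, j]` over consecutive position pairs and
normalizes each source row: `X[i, j] = N[i, j] / sum_j' N[i, j']`
(400 values, flattened with the source residue outer). Each fixed-source
block therefore sums to one; a zero denominator (impossible after
logistic normalization, kept defensive) emits zeros rather than an error.

**CSP-SegPseP-SegACP (700 features).** Three blocks over *segments* of
the profile:

* *Segmented pseudo-PSSM* (200 + 180). The profile is cut into two
  halves (split at `L1 = floor(L/2)`) or three thirds
  (`L1 = floor(L/3)`, remainder absorbed by the last segment; "equal
  segments" with integer rows forces some convention, and giving the
  remainder to the tail keeps the first segments exactly equal). Per
  segment and column, lag 0 is the segment mean and lag `lambda > 0` is
  the mean squared difference between entries `lambda` rows apart within
  the segment, `1/(n - lambda) * sum (P[i, j] - P[i + lambda, j])^2`,
  with `lambda` up to 4 on halves and up to 2 on thirds. Ordering is
  segment-outer, lambda-middle, column-inner.
* *Segmented autocovariance* (160 + 120). Per segment, column and lag
  `lg`, the mean product of deviations from the segment mean,
  `1/(n - lg) * sum (P[i, j] - m)(P[i + lg, j] - m)`, lags 1..4 on halves
  and 1..2 on thirds — correlation between residues `lg` apart.
* *Consensus sequence* (40). `X(i) = argmax_j P[i, j]` per row (ties to
  the lowest column index, for determinism), from which the composition
  `CSAAC_j = count(j)/L` and the composition moment
  `CSCM_j = (sum of 1-based positions where the consensus is j) / (L (L - 1))`
  are taken. The `L (L - 1)` denominator follows the standard
  composition-moment-vector convention.

The minimum accepted length is L = 10, which guarantees every lag window
(`lambda <= 4` on a half-segment) is nonempty. The fused table puts the
420 AATP columns first and the 700 CSP columns second (1,120 in total);
nothing downstream depends on that order, it is simply fixed.

Every encoder is verified in the test suite against an independent
brute-force loop implementation to 1e-12 on random profiles, and against
closed forms on constant profiles (uniform transitions, zero lag blocks).

## Class imbalance, without leakage

Real vesicular-transport benchmarks are roughly 1:3.6
positive:negative. The package implements three resamplers: edited
nearest neighbours (ENN; drops a majority sample whose 3 nearest
neighbours — Euclidean on z-scored features, since neighbour queries are
scale-sensitive — include any disagreeing label; `kind = "mode"` relaxes
this to a neighbour-majority vote), random undersampling to a target
ratio, and SMOTE (synthetic minority rows interpolated uniformly on
segments between minority neighbours). ENN is a *cleaning* method: the
resulting class ratio is a data outcome, so no ratio knob is exposed.
ClusterCentroids, NearMiss, SMOTEENN and SMOTETomek exist as named stubs
that fail loudly.

Because SMOTE invents rows and ENN deletes them, naive k-fold
cross-validation over a resampled table is biased: synthetic points
derived from a validation row leak its information into training.
`make_resampled_folds()` therefore resamples *inside* each training
split only; validation folds are untouched original rows and partition
the input exactly once. The test suite asserts this identity for both
resamplers, and `evaluate_holdout()` enforces the analogous id-disjoint
audit between train and test tables.

## MRMD feature ranking and selection

Each feature gets a *relevance* score (absolute Pearson correlation with
the label; constant features score 0) and a *distance* score (mean
Euclidean distance between its column and all other feature columns on
z-scored data, rescaled to [0, 1] by the maximum — higher means less
redundant). `score_sum` ranks by their sum.

The five link-analysis aggregations operate on a directed preference
graph whose construction is a package design choice. Nodes are features;
for each ordered pair there is an edge `u -> v` whenever `v` beats `u`
on at least one of three base orderings (relevance alone, distance
alone, their sum), pointing from loser to winner. Edges are weighted by
the total victory margin `sum_o max(0, s_o(v) - s_o(u))`: with bare
win-count weights, a noise feature that happens to be maximally
non-redundant collects weight from every other feature and HITS
authority localizes on it, whereas margin weighting lets decisive
relevance wins dominate marginal distance wins. On this endorsement
orientation, in-centrality measures quality: PageRank (damping 0.85) and
LeaderRank (PageRank after adding a ground node bidirectionally tied to
every feature) rank descending; TrustRank is personalized PageRank
restarted at the top relevance decile, ranking descending; HITS
authority (`hits_a`) ranks descending; and the HITS hub score
(`hits_h`) measures how strongly a feature endorses better ones — how
often it loses — so it ranks ascending. Ties break by relevance, then
feature index, making every ranking a deterministic permutation.

`select_subset()` walks top-k prefixes of a ranking over a k grid
(default every 10th dimension from 20), scores each with a caller-supplied
cross-validated metric, and returns the maximizing k (ties to the
smaller subset). When selection feeds model assessment it is fitted on
training splits only, inside each fold.

## Classifier and metrics

The classifier is gradient-boosted trees (XGBoost) with defaults
learning rate 0.1, 1,000 rounds, depth 8, `min_child_weight` 1, gamma 0,
row and column subsampling 0.8, binary-logistic objective and
`scale_pos_weight` 0.6 — after ENN cleaning the training classes remain
mildly imbalanced toward negatives, and the sub-unity weight keeps the
booster from over-correcting toward the positive class. Fits run single
threaded with an explicit seed so identical calls are bit-reproducible.

The metric suite reports ACC, sensitivity, specificity, precision and
MCC from the confusion counts at a decision threshold of 0.5 on the
predicted probability (no other threshold is singled out by the
protocol; 0.5 is the neutral choice). Undefined rates (empty
denominator) surface as `NaN` rather than a silent 0; MCC uses the
standard 0 convention when a denominator factor vanishes. Two AUC-like
numbers are reported and deliberately kept distinct: `paper_auc`, the
balanced accuracy `(Sens + Spec)/2` that this evaluation protocol prints
under the name "AUC", and `roc_auc`, the true trapezoidal area under the
empirical ROC of the continuous scores. They coincide exactly when the
scores are the binary predictions themselves (two-point ROC), which the
tests assert. Cross-validated results average per-fold metric reports
(not pooled confusions) over folds and then over repeats (default 3,
seeded `seed`, `seed + 1`, ...).

## The synthetic generator: what it does and does not show

`simulate_profiles()` draws raw integer scores from a discretized normal
(mean 0, sd 3, clipped to [-10, 13]), matching the magnitude range of
real BLOSUM-scaled profiles. Class signal enters two ways, mirroring the
two encoder families: a mean shift (`class_shift`, default 2) on columns
1-5 of positive profiles feeds the composition features, and an
argmax-transition bias (`transition_bias`, default 0.5: the probability
that a positive row is forced to share its argmax column with its
predecessor) feeds the transition and autocovariance features. Default
lengths are uniform on [50, 120], sized so both segmented encoders have
substantial windows while the whole pipeline stays desk-fast.

The generator emulates labeled profiles with class-dependent column
means and row-transition structure; it does not emulate phylogenetic
correlation between proteins, alignment-depth-dependent score variance,
compositional constraints between columns, or the homology redundancy of
real benchmarks. Passing the recovery tests therefore shows that the
pipeline's machinery extracts the kinds of signal it was built for and
reports chance when none exists — not that any particular accuracy will
be reached on curated sequence data, which requires externally computed
PSI-BLAST profiles.

Test and verification problem sizes are chosen to keep the full suite
desk-scale: recovery runs use 200 + 200 profiles with 5-fold CV and a
single repeat, oracle-equivalence runs use 50 random profiles with
L in [10, 40], and the planted-feature check uses 500 samples by 50
features. At these sizes the signal conditions are far from marginal
(recovered ROC-AUC is ~1.0, null ~0.5), so the pass/fail behaviour is
stable across seeds.

## Known limitations

* The tool consumes pre-computed PSI-BLAST ASCII profiles; it never runs
  PSI-BLAST nor bundles a sequence database.
* Only the 40-column ASCII PSSM dialect is parsed.
* The RPSSM, wavelet and second-order-moment encoder families are out of
  scope, as are the combined SMOTE-based cleaners and any deep-learning
  baseline.
* Published benchmark figures on the curated vesicular-transport dataset
  depend on that dataset and its NR-profile computation and are not
  reproduced here.
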