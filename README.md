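# vtpred

Identify vesicular transport proteins (VTPs) from evolutionary profiles.
VTPs ferry macromolecules between cellular compartments inside
membrane-bounded vesicles; recognising them computationally is much
cheaper than the experimental alternatives, and the evolutionary
conservation captured by a PSI-BLAST position-specific scoring matrix
(PSSM) is a stronger signal than the raw sequence. `vtpred` is an R
package and command-line tool for the full classification pipeline on
such profiles.

## What it computes

Given an L x 20 profile `P` (entry `P[i,j]` = substitution score of
position *i* into amino acid *j*, logistic-normalized into (0,1)):

* **AATP encoder (420)** — amino-acid composition
  `x_j = (1/L) Σ_i P[i,j]` (20) plus transition probability composition
  `X[i,j] = Σ_k P[k,i] P[k+1,j] / Σ_j' Σ_k P[k,i] P[k+1,j']` (400).
* **CSP-SegPseP-SegACP encoder (700)** — segmented pseudo-PSSM (segment
  means and mean squared lag-λ differences; 200 on two segments, 180 on
  three), segmented autocovariance at lags 1–4 / 1–2 (160 + 120), and
  consensus-sequence composition + composition-moment features from the
  per-row argmax (40).
* **Imbalance handling** — edited nearest neighbours (ENN), random
  undersampling and SMOTE, wired into cross-validation so that
  resampling touches *training folds only* (no synthetic or deleted row
  ever reaches a validation fold).
* **MRMD feature selection** — Max-Relevance (|Pearson r| with the
  label) Max-Distance (mean inter-feature Euclidean distance) ranking,
  aggregated by `score_sum` or by link-analysis centralities (HITS
  authority/hub, PageRank, TrustRank, LeaderRank) on a margin-weighted
  preference graph, with prefix subset search.
* **Classifier and metrics** — gradient-boosted trees (XGBoost;
  learning rate 0.1, 1,000 rounds, depth 8, subsample/colsample 0.8,
  `scale_pos_weight` 0.6, single-thread deterministic) and a metric
  suite reporting ACC, Sens, Spec, Precision, MCC, the balanced accuracy
  `(Sens+Spec)/2`, and the trapezoidal ROC-AUC.

A synthetic profile generator produces labeled PSSMs with class-dependent
column shifts and row-transition structure, so the entire pipeline is
testable without external databases. See the methods vignette
(`vignettes/vtpred-methods.Rmd`) for the models, conventions and design
rationale.

## Worked example

```r
library(vtpred)

# 60 positive / 120 negative synthetic profiles, lengths 50-120
sim <- simulate_profiles(synthetic_dataset_spec(60, 120, c(50, 120), seed = 42))
tb  <- extract_features(sim$profiles, sim$labels, encoder = "both")
tb
#> <feature_table> 180 samples x 1120 features (60 positive)

# leakage-free 5-fold CV: ENN cleaning and MRMD top-200 selection are
# re-fitted inside every training split
selector <- function(train) rank_features(train, "score_sum")$order[1:200]
cv <- run_cv(tb, k = 5, config = classifier_config(),
             resampler = enn_undersample, selector = selector,
             repeats = 1, seed = 42)
cv$report
#> <eval_report> tp=11.8 fp=0 tn=24 fn=0.2
#>   ACC=0.994 Sens=0.983 Spec=1.000 Prec=1.000 MCC=0.988 bAcc=0.992 ROC-AUC=1.000
```

The report averages per-fold confusion counts and metrics: of ~12
positive validation proteins per fold the model recovers essentially all
(Sens 0.983) with no false positives (Spec 1.000); `bAcc` is the
balanced accuracy `(Sens+Spec)/2` and `ROC-AUC` the threshold-free area
under the ROC curve. The synthetic classes here are well separated
(class shift 2, transition bias 0.5), so near-perfect recovery is the
expected outcome; with `class_shift = 0, transition_bias = 0` the same
pipeline reports chance-level ROC-AUC (~0.5).

Real profiles are consumed from PSI-BLAST ASCII PSSM files
(`parse_pssm()`; e.g. produced by
`psiblast -query seq.fasta -db nr -num_iterations 3 -out_ascii_pssm seq.pssm`),
with FASTA reading via `read_fasta()`. A thin CLI wraps the same
functions:

```sh
exec/vtpred simulate --n-pos 60 --n-neg 120 --out profs --seed 42
exec/vtpred extract  --pssm-dir profs --labels profs/labels.csv --encoder both --out feats.csv
exec/vtpred cv       --features feats.csv --out report.json --top-k 200
```

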