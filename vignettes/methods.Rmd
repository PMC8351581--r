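---
title: "Methods: sequence descriptors, feature engineering and model selection in pmpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence descriptors, feature engineering and model selection in pmpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmpred)
```

## The prediction problem

A moonlighting protein performs two or more unrelated functions with a
single polypeptide chain. `pmpred` treats their identification as
binary classification from sequence alone: no structure, no alignments,
no annotation. The working hypothesis — shared by the broader family of
sequence-based function predictors — is that short-range residue
patterns, above all tripeptide usage, carry a detectable trace of
multifunctionality. The pipeline makes that hypothesis testable rather
than assuming it: sixteen descriptor families are ranked head-to-head
and the classifier is built on whichever wins (tripeptide composition,
in every configuration we exercise).

## Descriptor families

All descriptors index the 20 canonical residues in the fixed order
`ACDEFGHIKLMNPQRSTVWY`. Sixteen families are implemented; their
dimensionalities are closed-form functions of their parameters:

| family | meaning | dimension (defaults) |
|---|---|---|
| TPC | tripeptide frequencies, `N_rst / (N-2)` | 8000 |
| GTPC | tripeptides over 5 physicochemical groups | 125 |
| CKSAAP | residue pairs at gaps 0..k_max | 400·(k_max+1) = 2400 |
| CKSAAGP | group pairs at gaps 0..k_max | 25·(k_max+1) = 150 |
| KSCTriad | conjoint-triad (7 classes) at spacings 0..k_max | 343·(k_max+1) = 2058 |
| DDE | dipeptide deviation from codon-based expectation | 400 |
| CTDC/CTDT/CTDD | composition / transition / distribution over 7 three-group properties | 21 / 21 / 105 |
| Moran, Geary, NMBroto | lagged autocorrelation of 8 residue scales | 8·nlag = 240 each |
| SOCNumber | sequence-order coupling numbers, 2 distance matrices | 2·nlag = 60 |
| QSOrder | quasi-sequence-order | 40 + 2·nlag = 100 |
| PAAC / APAAC | (amphiphilic) pseudo amino-acid composition | 20+λ = 50 / 20+2λ = 80 |

Parameter defaults — `k_max = 5`, `nlag = 30`, `λ = 30`, pseudo-composition
weight `w = 0.05` (0.1 for QSOrder) — are the common defaults of the
descriptor literature; all are overridable through `descriptor_spec()`.
Each family enforces its minimum sequence length (`N ≥ 3` for TPC,
`N > nlag` for order/autocorrelation classes, `N > λ` for the pseudo
compositions, `N ≥ k_max + 2` for gapped pairs, `N ≥ 2·k_max + 3` for
spaced triads) and raises an error rather than padding with zeros —
silent zeros would corrupt training.

Choices worth making explicit:

* **Frequency denominators.** Every count-type family divides by its
  own number of windows (`N-2` tripeptides, `N-k-1` k-gapped pairs,
  `N-2k-2` k-spaced triads), so composition blocks sum to exactly 1.
* **Residue scales.** Autocorrelations use eight published scales
  (Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, Grantham
  polarity and volume, isoelectric point, Chou–Fasman helix and sheet
  propensities, average residue mass), z-scored over the 20 residues
  with population (1/20) variance before lagging. The pseudo
  compositions use the classic triple hydrophobicity (Eisenberg),
  hydrophilicity (Hopp–Woods) and side-chain mass, standardized the
  same way.
* **Distance matrices.** SOCNumber and QSOrder require two residue
  distance matrices. We use (a) Grantham's chemical distance, computed
  from his published formula and component values (the computed matrix
  reproduces the printed table, e.g. L–I ≈ 5, W–C ≈ 215), and (b) a
  physicochemical distance defined as the root-mean-square difference
  of the three standardized pseudo-composition scales. Both are
  deterministic functions of published constants.
* **Degenerate inputs.** Moran and Geary autocorrelations are defined
  as 0 when the sequence has zero property variance (homopolymers);
  CTDD distribution features are 0 for absent groups, and the
  quartile occurrence ranks use `ceiling`, clamped to the occupied
  range.

Every family is checked against an independent brute-force counter
(explicit loops over windows, pairs and lags, counting with string
keys) on random sequences of lengths 35–500; agreement is exact to
1e-10 (relative for the raw coupling sums, whose magnitudes reach 1e7).

## Feature engineering

Three stages follow descriptor extraction, each fitted on training
rows only and replayed on validation or test data:

1. **Information-gain selection.** `IG = H(Y) − H(Y | bin(X))` in bits,
   with equal-frequency discretization into `min(10, distinct values)`
   bins. Bin edges are order-statistic quantiles, so IG is invariant
   under strictly monotone transformations of a feature — a desirable
   property for the heavily tied, skewed count ratios descriptors
   produce; empty bins merge. Features with IG > 0.05 bits are kept;
   when no feature clears the threshold the selector keeps the top
   80 % (`ceiling(0.8·p)`, ties broken by canonical column order, so
   builds are deterministic).
2. **Min-max normalization** to `[0, 1]` with training extremes.
   Constant features map to 0. Out-of-range values on new data are
   *not* clipped: the transform stays linear and the classifiers
   tolerate values outside the unit interval.
3. **PCA** to `min(10, p, n−1)` components (centering only — the
   preceding normalization already fixes the scale).

Cross-validation refits all three stages inside every fold. Fitting
them once on the full training set before splitting would leak fold
information into the selector and the projection; the leakage-safe
per-fold refit is the only defensible default, at the cost of slightly
pessimistic fold estimates on small data.

## Model selection and evaluation

Five classifiers are supported — XGBoost, SVM (RBF/linear), random
forest, decision tree and k-nearest neighbours (the supervised
classifier) — each with a small standard grid (`default_grid()`).
Hyperparameters are chosen by stratified 5-fold cross-validation;
stratification keeps class ratios within one sample per fold, which
stabilizes small-sample estimates. The selection metric is the mean
per-fold **AUPRC**: the positive (moonlighting) class is the rare and
valuable one, and the precision-recall curve penalizes false positives
on it far more sharply than the ROC curve does. Ties break by mean AUC
and then grid order.

AUPRC is the area under the precision-recall *step* curve (no
interpolation, ties grouped), whose random-scorer baseline is the
positive prevalence; AUC is the Mann–Whitney rank statistic (tie-aware,
identical to trapezoidal ROC integration). Sensitivity, specificity,
F1 and MCC are computed at the decision threshold (default 0.5, with
`score ≥ threshold` called positive); F1 and MCC are defined as 0 when
a denominator vanishes. Reports carry both pooled out-of-fold metrics
and per-fold means, since the two conventions differ on small folds.

SVMs obtain probabilities through e1071's built-in Platt scaling,
fitted by internal cross-validation inside each training fold. KNN
probabilities are vote fractions. The final model refits preprocessing
and classifier on the full training set with the selected
hyperparameters; `save_model()`/`load_model()` round-trip it with
score-identical behaviour (XGBoost boosters are stored in raw
serialized form).

## Data preparation utilities

`reduce_redundancy()` mirrors CD-HIT's greedy scheme: sequences are
visited longest-first and join the first existing representative whose
identity reaches the threshold (default 0.7), otherwise found a new
cluster. The default identity is a shared 5-mer containment score —
alignment-free, exact for duplicates, zero for k-mer-disjoint pairs —
with an optional global-alignment mode (`mode = "alignment"`) closer
to CD-HIT's alignment-based identity. `reduce_cross_redundancy()`
applies the same rule between a test set and a fixed training set.
`species_split()` assigns two-thirds of each species to training
(round half up, seeded shuffle). The k-mer identity is an acknowledged
approximation to CD-HIT's banded-alignment identity; at the thresholds
and sequence divergences exercised here the two agree on all planted
cluster structures.

## The synthetic generator

Real benchmark sets for plant moonlighting proteins are small, curated
and external; the test suite instead runs on synthetic populations with
controllable separation (`synthetic_config()` / `generate_proteins()`).
Defaults mirror the benchmark training composition: 103 positives, 155
negatives, lengths uniform on 35–500 (long enough for every descriptor
at default parameters).

* **composition-shift** draws residues i.i.d.: negatives uniform,
  positives uniform tilted log-linearly by `effect` along a fixed
  zero-sum unit direction (at `effect = 0` the classes are identical
  by construction; the tilt scale 0.5·effect gives a mild shift at
  effect 1 and a strong one at effect 8).
* **motif-spike** plants `Poisson(effect)` tripeptide motifs from a
  fixed 10-motif panel into each positive sequence; each negative
  receives the *same sampled letters* inserted at independent
  positions. Single-residue composition is therefore identical across
  classes by construction, and the class signal lives in tripeptide
  usage. Because dipeptide frequencies are marginals of tripeptide
  frequencies, pair-based families (CKSAAP, DDE) unavoidably see a
  weakened shadow of the signal — which is precisely what makes the
  feature-class ranking informative: TPC sees the joint pattern and
  wins, the pair classes trail it.

The generator emulates class-conditional compositional structure and
nothing else: no species structure, no GO semantics, no homology, no
length–class correlation beyond sampling noise. Tests passing on it
show that the pipeline recovers compositional signal when present and
reports chance when absent; they cannot certify performance on real
curated benchmarks, whose signal may be weaker, confounded or
homology-driven.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run at desk scale, chosen
so the full suite completes in a couple of minutes on one core:
descriptor oracles on 50 sequences of lengths 35–500; signal-recovery
and ranking fixtures of 40+40 sequences (lengths 35–120, motif-spike
effect 8); null calibration on ten label-permuted sets of 100+100.
Descriptor agreement is asserted at 1e-10, PCA orthonormality at 1e-8,
metric identities at double precision; chance-level calibration is
asserted within ±0.1 of AUC 0.5 and of the prevalence AUPRC baseline.

## Known limitations

* The k-mer identity underestimates alignment identity for diverged
  homologs; use `mode = "alignment"` when fidelity to CD-HIT matters
  more than speed.
* Information gain is univariate; interacting features that are
  individually uninformative are discarded before PCA can combine
  them.
* With fewer than ~10 samples per class, per-fold AUPRC is extremely
  coarse and grid search will often tie; the tie-break then decides.
* Probability calibration for SVM (Platt) and KNN (vote fractions) is
  coarse on small folds; ranking metrics are unaffected, threshold
  metrics less so.
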