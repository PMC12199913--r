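---
title: "Moment-based window encoding and ensemble classification of RNA 2'-O-methylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based window encoding and ensemble classification of RNA 2'-O-methylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmpred)
```

## The problem

2'-O-methylation (Nm) adds a methyl group to the ribose 2'-hydroxyl of an
RNA nucleotide.  It occurs at A, C, G and U positions of tRNA, mRNA and
miRNA, stabilises RNA structure and is linked to disease, but mapping Nm
sites experimentally (e.g. by mass spectrometry) is slow.  `nmpred`
implements a sequence-only predictor: a candidate site is represented by the
41-nt window centred on it (the site at 1-based position 21, twenty
nucleotides of context on either side), the window is encoded into a fixed
522-dimensional vector, and a supervised classifier separates methylated
from unmethylated windows.  Because Nm site propensity is nucleotide
specific, one model is trained per centre base, mirroring the four
nucleotide-specific benchmark datasets (A2OM, C2OM, G2OM, U2OM).

## The encoder

All k-mer machinery uses the RNA alphabet ordered `A < C < G < U`, k-mer
orders k = 1, 2, 3, and overlapping tokenisation with step 1, so a 41-mer
contributes 41 mononucleotides, 40 dinucleotides and 39 trinucleotides.
A k-mer's index is its lexicographic rank (base-4 digits A=0, C=1, G=2,
U=3, first character most significant).

Six descriptor blocks are concatenated, in this fixed order:

| block | columns | content |
|---|---|---|
| PRIM moments   | 1–90    | moment blocks of the k = 1, 2, 3 PRIM matrices |
| RPRIM moments  | 91–180  | same on the reversed sequence |
| frequency (FV) | 181–264 | overlapping k-mer counts, `[4 | 16 | 64]` |
| AAPIV          | 265–348 | per-k-mer sums of 1-based occurrence start positions |
| RAAPIV         | 349–432 | AAPIV of the reversed sequence |
| 2-D matrix moments | 433–522 | moment blocks of the 7×7 code matrices |

The **position-relative incidence matrix** (PRIM) of order k is the
`4^k × 4^k` matrix whose entry `(i, j)` accumulates, over every occurrence
of k-mer *j* at start position *p*, the offset `p − first(i)` from the
first occurrence of k-mer *i*.  Offsets may be negative and a row is
identically zero when its k-mer is absent.  The reverse variant (RPRIM) is
the same construction on the reversed residue string, which gives the exact
identities `RPRIM(w, k) = PRIM(reverse(w), k)` and
`RAAPIV(w) = AAPIV(reverse(w))` that the test suite checks against
brute-force nested-loop oracles.

The **2-D code matrix** reshapes the 1-based k-mer code sequence row-major
into the smallest square that holds it (`N = ceiling(sqrt(len))`, i.e.
7 × 7 for every k on 41-mers), padding trailing cells with 0 so padding
carries no intensity.

## Moment reduction

Each square matrix is reduced to 30 numbers: raw, central and Hahn moments
for the ten exponent pairs `(u, v)` with `u + v ≤ 3`, in the fixed order
`(0,0), (0,1), (1,0), (1,1), (0,2), (2,0), (1,2), (2,1), (0,3), (3,0)`.
Ten pairs — rather than a shorter explicit list — is what makes the block
arithmetic close: 3 matrices × 3 families × 10 orders = 90 features per
matrix block, and 90 + 90 + 84 + 84 + 84 + 90 = 522.

Raw moments are index-weighted sums `L_uv = Σ_a Σ_b a^u b^v β_ab` over
1-based grid indices; central moments are the same sums about the intensity
centroid `(L10/L00, L01/L00)`, so `n10 = n01 = 0` identically.  A matrix
whose entries sum to zero (possible for PRIM, whose offsets can cancel) has
no centroid; its central moments are defined as all-zero.  The low-level
functions warn in that case, while the bulk encoder treats it as the
expected convention and stays quiet.

**Hahn moments.**  The discrete Hahn polynomials are implemented in their
classical hypergeometric form

```
h_n^(u,v)(r, N) = (N+v−1)_n (N−1)_n · 3F2(−n, n+u+v+1, −r; u+1, −(N−1); 1)
```

with rising factorials `(x)_k` computed in log space with sign tracking.
This family is orthogonal on `r = 0..N−1` under the weight
`w(r) = C(u+r, r)·C(v+N−1−r, N−1−r)`; at `u = v = 0` it reduces to the
discrete Chebyshev polynomials (uniform weight) with the closed form
`h_1(r) = (N−1)² − 2r(N−1)`.  Orthonormalised polynomials are
`h̃_n(r) = h_n(r)·sqrt(w(r)/ρ_n)` with the squared norm `ρ_n` evaluated by
its defining (finite, exact) sum, and the Hahn moments are the projections
`H_ij = Σ_q Σ_p β_qp h̃_i(q) h̃_j(p)`.  Transcriptions of these polynomials
vary across the descriptor literature and are not always orthogonal as
printed, so the package trusts no single formula: orthonormality of the
basis (identity Gram matrix to 1e−8) and exact analysis/synthesis
round-trips at full order are asserted numerically in the test suite.
The shape parameters default to `u = v = 0` and are configurable; nothing
in the feature definition requires otherwise.

## Scaling and classifiers

Feature tables are standardised per column (z-scores with population
standard deviation; columns constant in training map to 0).  The scaler is
fitted inside `nm_fit()` on the training rows only and stored with the
model, so no scaling statistic can leak across a train/test boundary —
cross-validation refits it inside every training fold.

The registry (`nm_models()`) holds the study's eight ensemble classifiers —
bagging family: random forest, extremely randomised trees, a single
decision tree, and bagged trees; boosting family: gradient boosting,
histogram-based gradient boosting, AdaBoost, XGBoost — plus five
conventional baselines (random forest, RBF-kernel SVM, 5-nearest
neighbours, a feed-forward neural network, decision tree).  Implementation
notes:

* *Bagged trees* exploit the identity between bagging and a random forest
  that samples **all** features at every split (`mtry = p`), with 100
  trees by default.
* *AdaBoost* is the discrete SAMME algorithm over depth-1 stumps (50
  rounds, learning rate 1), implemented in the package.
* The three gradient-boosting variants are configured growths of the same
  boosted-tree engine: classic (depth 3, shrinkage 0.1, exact splits),
  histogram-based (31-leaf loss-guided growth on binned features), and the
  engine defaults (depth 6, shrinkage 0.3).
* The *neural network* baseline uses a single hidden layer of 8 units.
  With 522 inputs the weight count grows by ~523 per hidden unit, and the
  dense quasi-Newton optimiser behind the fitter scales quadratically in
  memory with the weight count; 8 units (~4200 weights) keeps the model
  well-posed for the few-hundred-row training sets this package targets
  while still allowing a non-linear decision boundary.  The size is a
  hyperparameter (`params = list(size = ...)`).

Training is seeded end to end: equal `(data, model, params, seed)` give
identical predictions.  Scores are probabilities in [0, 1]; the hard call
is `score ≥ 0.5` (no threshold tuning is attempted).

## Evaluation protocols

`nm_metrics()` implements sensitivity, specificity, accuracy and the
Matthews correlation coefficient with the standard degenerate-case
conventions: MCC is 0 whenever a factor of its denominator vanishes, and a
sensitivity (or specificity) whose denominator is empty is reported as
`NA` — undefined, not zero.  ROC curves sweep the unique scores as
thresholds; tied scores contribute trapezoid midpoints, which makes the
integrated AUC equal the Mann–Whitney rank statistic (asserted against an
exhaustive pair-counting oracle).

Both protocols stratify by class, since the nucleotide-specific datasets
must keep both classes in every partition.  The independent test reserves
`round(0.2 · class size)` rows per class.  K-fold assignment balances fold
sizes to within one row overall by giving each class's remainder to the
currently smallest folds — 103 rows in 5 folds always split 21/21/21/20/20.

## The synthetic benchmark generator

`nm_simulate()` emulates the structure the nucleotide-specific Nm
benchmarks exhibit in their sequence logos: a fixed centre base at
position 21 and, in positive windows, enrichment of guanine in the
downstream half (positions 22–41), with uniform background elsewhere and
throughout negative windows.  Defaults: 200 positives + 200 negatives,
`p_enriched = 0.9`, uniform background 0.25 per base.  Setting
`p_enriched` to the background probability produces a signal-free dataset
(the "evenly distributed" U-centred case), which doubles as a leakage
control: any pipeline that beats chance on it is broken.

Positions are drawn independently given the class.  This deliberately
ignores inter-position dependence, codon structure and compositional bias
of real transcriptomes, so a passing pipeline demonstrates correct signal
propagation through encoder, scaler, classifier and protocol — not
real-data accuracy.  Published accuracies on the real benchmarks are
neither reproduced nor contradicted by these tests.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at deliberately modest sizes,
chosen as representative rather than exhaustive: 200+200 windows per
enriched dataset, 100+100 for null controls and registry sweeps, 10 null
seeds, 50-matrix moment-oracle sweeps, 100-window identity sweeps and a
10,000-case metric fuzz.  Exact integer identities (PRIM/RPRIM, AAPIV,
frequencies) are asserted with `identical()`; floating-point oracles at
1e−9, basis orthonormality at 1e−8, full-order round-trips at 1e−6.  The
null-control criterion is asserted on the mean held-out accuracy over the
10 seeds (each 40-row test split has a binomial standard deviation of
~0.08 under the null, so per-seed bounds would trip by chance; the mean has
standard deviation ~0.025).

## Known limitations

* The encoder is defined for exact 41-nt windows; scanning handles longer
  sequences, but sites closer than 20 nt to a sequence end are not scored
  (no padding convention is defined).
* Ambiguity codes (N, R, Y, ...) are rejected rather than expanded.
* Feature blocks enter the model as raw integers/moments before dataset
  standardisation; no per-window normalisation is applied.
* Hyperparameters are fixed ecosystem defaults recorded in the fit object;
  no tuning or early stopping is performed.
* Model files are R serialisations intended for same-version round-trips;
  a version tag guards against silent cross-version loads.
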