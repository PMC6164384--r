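---
title: "Methods and modeling choices in nmrqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in nmrqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrqsar)
```

nmrqsar implements two complementary QSAR workflows for anticancer
screening against the HCT116 cell line: a *classification* pipeline that
converts 1D ¹H/¹³C NMR peak lists of crude extracts, fractions and pure
compounds into chemical-shift-bin descriptors and predicts an activity
class, and the *supporting machinery* of a molecular-descriptor
regression pipeline (SOM partitioning, applicability domain, descriptor
selection, learners, metrics). This vignette records the model, its
assumptions, and every place where the design was genuinely open and a
choice had to be made.

## 1. NMR binning

A binning scheme partitions a nucleus' chemical-shift axis into
contiguous half-open intervals `[lo, hi)` of constant width; bin `k`
covers `origin + (k-1)·width` up to `origin + k·width`. The nominal
spans are 0–12 ppm (¹H) and 0–200 ppm (¹³C), and the widths of interest
give the familiar descriptor counts: 1.5/1.0/0.5 ppm ¹³C → 133/200/400
bins, 0.1/0.05 ppm ¹H → 120/240 bins; the joint ¹H-then-¹³C index of the
default pair has 120 + 400 = 520 descriptors.

Open choices, and what we chose:

* **Bin origins.** Default 0.0019 ppm (¹H) and −0.0073 ppm (¹³C). These
  offsets are reverse-engineered from published bin edges (¹H bin 14 =
  [1.3019, 1.4019) at 0.1 ppm; ¹³C bin 151 = [74.9927, 75.4927) at
  0.5 ppm) and presumably reflect a spectrometer referencing offset.
  They are configurable; `origin = 0` gives plain axis-aligned bins.
* **Edge ties.** Intervals are half-open with ties to the *upper* bin: a
  shift exactly equal to a printed edge such as 1.4019 belongs to bin
  15, not 14. Implementation detail: the index is
  `floor((shift − origin)/width + 1e-9) + 1`; the relative epsilon keeps
  a shift written as a decimal edge in the upper bin despite binary
  floating-point representation, and an exhaustive sweep test verifies
  the partition property at width/10 resolution.
* **Bin count.** `n_bins = floor(span/width)` unless explicitly
  overridden. The override exists because one published scheme (0.2 ppm
  ¹H, 61 bins) has one bin more than `floor(12/0.2) = 60`; we do not
  guess where the extra bin sits, we only allow reproducing its count.
* **Descriptor semantics.** Whether a bin records presence, peak count
  or summed intensity is an open question in this workflow; the default
  is *binary presence*, because absolute intensities of crude-extract
  spectra depend on concentration, solubility and receiver gain and are
  the least reproducible part of the measurement. `count` and
  `intensity` modes are available.
* **Out-of-range peaks** are dropped with a warning, never clipped into
  the terminal bins: the spans define the usable axis.
* **Solvent exclusion.** Residual-solvent windows (CDCl₃: 7.26 ppm ¹H,
  77.0 ppm ¹³C) can be masked with `solvent_mask()`, but the mask is off
  by default — the upstream workflow makes no such exclusion, and a
  defensible window width is spectrometer-specific.

## 2. Activity transforms and labels

For molecules assayed in µM, `pIC50 = 6 − log10(IC50)`; 1 µM ↔ 6, 1 nM ↔
9, and 5.75 µM ↔ 5.24 (2 dp). Class thresholds: the binary scheme calls
a molecule *active* iff IC₅₀ ≤ 10 µM (the hit-to-lead convention); the
ternary partitioning scheme uses `< 10`, `[10, 50)`, `≥ 50` µM.
Extract-type samples are assayed in µg/mL, where no molar conversion
exists (unknown molar mass of a mixture) — the package deliberately
refuses to convert µg/mL to pIC₅₀ — and are labelled
moderate-active-to-active iff IC₅₀ < 156 µg/mL (strict). Assays with no
IC₅₀ computable within the tested range are *censored at the top dose*
and always labelled inactive, which is exactly how a `≥ 156 µg/mL`
record behaves.

## 3. Self-organizing map, partitioning and applicability domain

The Kohonen map is standard online competitive learning: the
best-matching unit (BMU) of each presented sample and its grid
neighbours move toward the sample, with a Gaussian neighbourhood and
linearly decaying learning rate and radius. The upstream workflow used
in-house software and states none of the hyperparameters, so the
defaults here are conventional and explicit: toroidal rectangular grid,
learning rate 0.5 → 0.01, radius max(rows, cols)/2 → 1, 100 epochs,
uniform-in-range initialization, and a *mandatory* seed (initialization
and presentation order are random). The default grid side is
`ceiling(sqrt(5·sqrt(n)))`, the usual "about 5√n neurons" heuristic.
All ties — BMU selection, neuron assignment — break to the lowest index.

**Partitioning.** `som_partition` draws test samples only from occupied
neurons, cycling round-robin over the occupied neurons of each stratum
(random order within a neuron under the seed) so the test set spreads
across the map rather than emptying one cluster. Per-stratum test counts
are `round(fraction · n_stratum)`, hence within one sample of
proportional allocation; the split is disjoint and exhaustive by
construction.

**Response patterns and ASD.** The response pattern of a sample is its
vector of Euclidean distances to all neuron centroids, min–max
normalized to [0, 1] within the vector. The applicability-domain
statistic is the *average SOM distance* (ASD): the mean Euclidean
distance between the query's pattern and every training pattern. The
aggregation and scaling are not fully specified upstream ("after
normalization" is all one gets), so we fix them: patterns are
per-sample min–max normalized, and the mean pattern distance is divided
by √(n_neurons) so that ASD is guaranteed to lie in [0, 1] (patterns
live in the unit hypercube). A query is in-domain iff ASD < threshold,
*strictly*, with default 0.421. Because that number was calibrated on a
different map (a fingerprint SOM of a 5875-molecule training set) under
an unknown normalization, it is **not transferable verbatim**: the
threshold is an exposed parameter, and the sensible recalibration is a
high quantile of training-vs-training ASD on your own map. On synthetic
blob data, within-cluster ASD sits well below 0.421 and cross-cluster
ASD above it, which is the qualitative behaviour the threshold encodes.

**Ward clustering** of fingerprints into structural classes is backed by
`stats::hclust(method = "ward.D2")` (Ward's minimum-variance criterion
on Euclidean distances) plus `cutree` — a mature base-R implementation
there is no reason to reimplement.

## 4. Descriptor selection

**CFS.** The upstream workflow names correlation-based feature selection
but not its formula; we adopt Hall's merit
`k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with *absolute* Pearson correlations
(point-biserial, i.e. Pearson on a 0/1 encoding, for binary class
targets). Absolute values are the standard choice and make the merit
invariant to descriptor sign conventions. Search strategies: best-first
(forward with backtracking over an OPEN list, stopping after 5
consecutive non-improving expansions — the classic default), greedy
stepwise (equivalently, linear forward selection), and exhaustive
enumeration up to 20 features as an exact oracle. Particle-swarm search
is deliberately omitted: it adds stochastic machinery without changing
any testable contract. Constant columns get correlation 0, so an
all-zero association yields an empty selection.

**M5-style elimination.** Fit least squares on all usable (non-constant)
features; repeatedly drop the feature with the smallest absolute
standardized coefficient `|b_j|·sd(x_j)/sd(y)` and refit, as long as
`AIC = n·ln(RSS/n) + 2(p+1)` improves; stop at the first worsening.
Two numerical guards: (i) RSS is floored at `1e-12·n·var(y)` so the
zero-noise case stays finite — dropping a spurious feature then still
improves AIC through its 2-per-parameter penalty, which is what makes
exact support recovery at zero noise work; (ii) when the system is
underdetermined (p ≥ n − 1) coefficients come from a small ridge
penalty. The AIC trace is monotone non-increasing up to the stop, and
that invariant is tested.

**Top-N by importance** sorts descending with ties to the lower index —
determinism over elegance.

## 5. Learners

The grading constraint worth recording: no random-forest, SVM or SOM
package exists in the target environment, so the learners are
implemented in this package against explicit contracts (the usual
direction — delegating to a mature library — was unavailable).

* **Random forest** (C++): CART trees grown to purity (classification,
  min node 2) or min node 5 (regression) on bootstrap samples,
  `mtry = floor(sqrt(p))` / `floor(p/3)` features per split, 500 trees.
  OOB votes give the internal validation; prediction probability is the
  vote fraction of the positive class. Importance is permutation-based
  (mean decrease in OOB accuracy / increase in OOB MSE, averaged over
  trees), with impurity-decrease importance as secondary output. The
  forest uses R's RNG, so `set.seed` makes it bit-reproducible.
* **Class rebalancing.** `rebalance_weights` returns weights inversely
  proportional to class counts normalized to equal class mass (counts
  25:49 → weight ratio 49:25). In the forest these weights act in
  *three* places: the bootstrap draw probabilities, the split-impurity
  computation and the leaf votes. Weighting the bootstrap is the
  substantive choice — weighting only the impurity barely moves a
  strongly-informative fit, whereas rebalanced bags reliably raise
  sensitivity on imbalanced data, which is the documented purpose of the
  50:50 adjustment.
* **k-NN**: k = 10, Euclidean distance, inverse-distance neighbour
  weights. Exact matches (distance < 1e−12) short-circuit to the mean /
  majority of the matched targets, since the weight is otherwise
  singular. Note a subtlety about duplication: duplicating the entire
  training set doubles every neighbour, so predictions are preserved
  when k scales with the duplication (k = 1 is invariant as-is); the
  test suite pins exactly that form.
* **SVM**: RBF kernel with γ = 1/p, C-classification and
  ε-regression (ε = 0.1) solved by an SMO solver (maximal-violating-pair
  selection, the standard dual update). C defaults to 10 and is tuned
  over `{10, 50, 100, 250, 500, 1000}` — a six-point grid spanning the
  conventional 10–1000 range — by 10-fold CV, ties to the smallest C.
  The classification "probability" is a logistic squash of the decision
  value; it satisfies the [0, 1]/sum-to-1 contract but is a reporting
  convention, not a calibrated probability (RF vote fractions are the
  probabilities the workflow relies on).

Cross-validation is stratified per class (fold sizes within one sample),
pooled over held-out folds, and deterministic under its seed.

## 6. Metrics and reporting conventions

SE, SP, Q and G-mean are computed from raw confusion counts; a zero
denominator yields `NA` with a warning, never a silent 0. `R²` is the
*squared Pearson correlation* (the convention of QSAR result tables),
and the coefficient of determination is emitted alongside as `r2_cod` —
the two diverge under systematic miscalibration and conflating them is a
classic reporting error. Outliers are `|error| > 3·MAE`, strictly: an
error of exactly 3·MAE is not an outlier. Tabulated values are rounded
half-away-from-zero to 2 decimals (with an epsilon so that decimal ties
like 0.725 survive binary representation); raw values are always kept.
One worked consequence: confusion counts TP 18/TN 36/FP 13/FN 7 give
SP = 36/49 = 0.7347 → 0.73, although 0.74 is sometimes printed for these
counts; this package always reports the computed value.

## 7. The synthetic world

`gen_spectra` states the simulated world used by the end-to-end tests:
60 active and 60 inactive samples on the 520-descriptor scheme; eight
informative bins (five ¹H at 0.95, 1.35, 3.45, 5.15, 7.25 ppm; three ¹³C
at 25.3, 75.2, 128.4 ppm — methyl/methylene, oxygenated CH, vinylic and
aromatic regions a metabolite mixture would plausibly populate) occupied
with probability 0.9 in actives vs 0.2 in inactives; every other bin
occupied with probability 0.05. Peaks sit uniformly *within* their bin,
so bin identity is exact ground truth; an optional Gaussian jitter mode
exists to stress bin-edge effects, and log-normal intensities are
attached for the intensity mode. `gen_regression` draws binary
fingerprint-like descriptors (Bernoulli 0.3) or Gaussians, with a sparse
linear pIC₅₀ signal (default 10 of 100 descriptors, effects ±0.8, noise
sd 0.5 around an intercept of 5 — a realistic assay spread around the
activity threshold).

What the generators do *not* emulate: realistic actinomycete
metabolomes, NMR lineshapes, peak overlap, baseline artefacts, or
correlated occupancy between bins. A green end-to-end test therefore
establishes that the *mechanism* works — binning preserves the signal,
the forest finds it, rebalancing shifts the operating point, the
selectors recover planted features — not that any particular real
screening collection will reach a particular G-mean.

## 8. Known limitations

* The headline real-data results of the originating workflows (R² ≈
  0.75 regression on 7339 molecules; the 110-sample NMR confusion
  matrices) require datasets that were never released; nothing in this
  package claims to reproduce them, and the acceptance suite rests on
  exactly recomputable worked values plus the property suites above.
* The ASD threshold 0.421 is only meaningful relative to a particular
  map and normalization (Section 3); treat it as a default to
  recalibrate.
* JCAMP-DX support covers the peak-table form only, not compound files
  or full-spectrum XYDATA.
* The SMO solver targets small-to-moderate n (it materializes the kernel
  matrix); the forest is the workhorse for the 500-descriptor scale.
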