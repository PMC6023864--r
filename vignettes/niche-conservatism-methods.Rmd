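---
title: "Methods: testing climatic-niche conservatism with paleoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing climatic-niche conservatism with paleoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoniche)
```

## The question and the two tracks

Hindcasting a species distribution model (SDM) assumes the realized
climatic niche is conserved across time slices. `paleoniche` tests that
assumption two ways, on the same data:

1. **Geographical track.** SDMs calibrated in one scenario are
   projected, with clamping, onto the other scenarios and validated
   against independent presences from those periods (fossil records, or
   current records for the reverse direction). A conserved niche yields
   external AUC comparable to internal AUC; a shifted niche yields
   external AUC near or below chance while internal AUC stays high.
2. **Environmental track.** All scenarios are pooled into a single
   two-axis PCA climate space. For each period a kernel occupancy grid
   is built and niches are compared with Schoener's D, equivalency and
   similarity randomization tests, dynamics indices
   (expansion/stability/unfilling) and centroid-shift vectors.

The agreement of the two tracks is the substantive result: transfer
failure alone can be an artifact of non-analogue climate (which the
MESS surface diagnoses), while overlap indices alone can be driven by
availability changes (which the o/e correction and the similarity null
address).

## Models

### Polynomial logistic GLM

A binomial-logit fit on per-variable polynomial expansions (powers
1..`degree`, default 2, no cross-products), standardized with
weight-aware constants so that integer row weights are exactly
equivalent to row duplication. With a background contrast the contrast
rows are down-weighted to m/N (m presences, N background rows), giving
presence and contrast equal total mass — the "weighted background"
design. The fit metric is explained deviance D² = 1 − dev/dev₀.
Complete separation triggers a ridge-penalized refit (L2 = 1e−6) with a
warning rather than unbounded coefficients.

### Random forest

A regression forest on the 0/1 labels against pseudoabsences
(default count = number of presences). The fit metric is out-of-bag
variance explained, 1 − MSE₍oob₎/Var(y); variable importance is the
permutation (%IncMSE) diagnostic. Regression on the probability scale,
rather than classification, keeps the output a continuous suitability.

### Maxent-style penalized log-linear density

The model maximizes
(1/m) Σ₍pres₎ λ·f(x) − log Σ₍bg₎ (1/N) e^{λ·f(x)} − Σ_k β_k |λ_k|
with per-feature penalties β_k = r·sqrt(var₍bg₎(f_k)/m) and
regularization multiplier r = 3 by default. Presence samples are added
to the background sum, as in the reference Maxent implementation; this
bounds the objective even for separable data. Features are linear and
quadratic terms of background-standardized variables (forward hinge
features at background quantiles are available but off by default — the
smaller feature set is easier to interpret and regularize at fossil
sample sizes). The convex problem is solved by FISTA proximal gradient
with backtracking; convergence is declared on the KKT conditions of the
L1 problem, and the soft-threshold step produces exact zeros, so an
overwhelming penalty returns the null model with gain 0. The fit metric
is the gain (the two likelihood terms at the optimum). Suitability
output is the logistic transform of the linear score — a monotone
transform, so AUC, Spearman comparisons and D are unaffected by the
choice.

### Clamping and MESS

Cross-scenario projections truncate each variable to its training range
by default ("clamping"), so out-of-range conditions receive the
range-edge response instead of an uncontrolled extrapolation. The MESS
surface makes extrapolation explicit: per cell and variable, with
f = 100·(#reference < v)/N, similarity is 100(v−min)/(max−min) when
f = 0, 2f when f ≤ 50, 2(100−f) when f < 100, and 100(max−v)/(max−min)
when f = 100; the cell value is the minimum over variables and is
negative exactly where some variable leaves its calibrated range. The
MoD grid records the argmin variable, ties resolved to the first
variable in stack order.

## Environmental-space framework

All scenario cells are pooled, standardized by the pooled mean/SD, and
the first two eigenvectors of the correlation matrix define the space
(axis signs fixed so the largest-magnitude loading is positive).
Exactly two axes are used.

Each niche is an R × R grid (R = 100 by default) over an extent covering
the pooled background scores of the entities compared, padded 5%.
Occurrence density o and environment density e are Gaussian kernel
estimates with per-axis normal-reference ("plug-in") bandwidths on the
respective score sets; corrected occupancy is z = o/e, rescaled to
maximum 1. Two numerical guards matter in practice:

* **e-support truncation.** z is only formed where e exceeds the level
  below which 0.1% of the total e mass lies. Without it, the far
  numeric tail of the e kernel produces unbounded o/e spikes in cells
  holding essentially no environment, and D between any two grids
  collapses toward 0.
* **Membership contour.** For the dynamics indices, "niche membership"
  is the smallest cell set holding 95% of the z mass — the kernel
  utilization-distribution convention used for home ranges. A literal
  z > 0 rule is degenerate for smooth kernels (every cell has a tiny
  positive tail, so expansion would always be 0); `membershipMass = 1`
  restores it.

Schoener's D = 1 − ½ Σ |p_a − p_b| is computed on corrected occupancy by
default: the periods compared offer different available climates, which
is precisely what the correction absorbs. The uncorrected
(occurrence-density) variant is a switch.

### Randomization tests

**Equivalency** pools the two occurrence sets and reassigns records to
groups of the original sizes, rebuilding both grids against their fixed
backgrounds; p = (1 + #{D_null ≤ D_obs})/(replicates + 1), one-sided
lower, 100 replicates by default. Two design points:

* A single occurrence-kernel bandwidth, computed from the pooled
  occurrence scores, is used for the observed and all null grids —
  otherwise the observed assignment would not be exchangeable with the
  replicates.
* The reassignment respects spatial thinning. Thinned datasets contain
  at most one record per cell, so a record appearing in both datasets
  is pinned one-copy-per-group and only singletons are shuffled. An
  unconstrained permutation can place both copies in one group — a
  configuration the observed data cannot attain — which biases null D
  downward and makes the test severely conservative (measured rejection
  0 instead of ≈5% under the null).

With both samples drawn in one scenario the test holds its nominal
size. Across two different scenario realizations it is deliberately
sensitive: any availability-induced difference in the realized niches
is detected, and conserved-truth species are still rejected in roughly
a third of runs. That is a property of the equivalency hypothesis
(realized niches identical), not an artifact — on real data the
analogous tests reject for every period pair — and it is why the
similarity test, not equivalency, carries the conservatism question
across scenarios.

**Similarity** compares one entity's observed grid with grids built
from random draws for the other entity. The default null follows the
literal construction — |b| occurrences gathered at random from b's
available environment — with p = (1 + #{D_null ≥ D_obs})/(replicates+1)
for the "more similar than chance" alternative; the pipeline runs both
directions. A centroid-shift null (translate b's occurrence cloud to a
uniform random centroid, preserving its shape) is available via
`nullModel = "shift"`.

The (1 + k)/(n + 1) p-value convention avoids p = 0 at finite
replicates, so reported p-values always lie in (0, 1].

### Dynamics and centroids

Within the analogue region (both e > 0 after support truncation, or a
quantile of positive e via `analogQuantile`), expansion is the
z-weighted fraction of the paleo niche outside current membership,
stability its exact complement, and unfilling the mirrored fraction of
the current niche absent from the paleo niche. Centroid shifts are
density-weighted means of o (occurrence centroid) and e (extent
centroid) in score space.

## The synthetic generator

The generator emulates what the analysis needs from real data, not the
data themselves:

* **Climate fields.** Seeded Gaussian white noise per variable,
  low-pass filtered to an autocorrelation length (Gaussian kernel SD in
  cells, default 6), then empirically orthogonalized (QR) and mixed by
  the Cholesky factor of the target correlation matrix — so sample
  cross-correlations match the target essentially exactly, and the
  ±0.05 recovery property holds by construction rather than luck.
  Fields are scaled to Iberian-like baselines (e.g. temperature
  seasonality 5500 ± 900, quarterly temperatures ≈ 12–17 ± 5–6 °C,
  quarterly precipitation 70–250 ± 35–90 mm). An optional linear
  north-south gradient is available (off by default; it perturbs the
  realized correlations).
* **Scenarios.** Cellwise affine offsets. The Last Interglacial
  analogue applies +3.8 °C to the quarterly temperature variables and a
  16% precipitation reduction; the glacial analogue is −5 °C with
  slightly reduced precipitation, and the mid-Holocene analogue +0.8 °C
  and slightly moister. Only the Interglacial contrast has quantitative
  anchors; the other two presets are qualitative choices.
* **Species.** A Gaussian response s(x) = maxPrevalence ·
  exp(−½ Σ ((x_j−μ_j)/σ_j)²). Default tolerances are roughly two thirds
  of the regional SD per variable — a habitat specialist, matching the
  kind of organism for which this question is typically asked, while
  leaving a broad low-suitability fringe for the models to rank. Occurrences
  are drawn without replacement at cell resolution with probability
  proportional to suitability (404 current records by default; fossil
  defaults 28/16/13 per paleo scenario), so downstream thinning is
  exercised but not degenerate.
* **Niche shift condition.** The "shifted" species displaces the niche
  optimum by k pooled standard deviations (default k = 2) along the
  leading axis of the pooled climate PCA (`nicheShiftVector`). A raw
  single-variable displacement is partly invisible to the 2-axis
  analysis plane and partly erased by availability weighting of the
  realized niche; displacing along PC1 makes the nominal magnitude the
  effective one.

What the generator does **not** emulate: topography and coastlines,
anisotropic or non-stationary spatial covariance, observation bias in
occurrences, dating uncertainty in fossils, and truncation of the
fundamental niche beyond what availability weighting induces. Passing
recovery tests on synthetic data therefore demonstrates the estimators
are correct and calibrated under known truth — not that real fossil
records are unbiased samples.

## Numerical and design choices

* Grid convention: row 1 is the northernmost row; the origin is the
  lower-left corner; cells are half-open so boundary points belong to
  the cell right/above. Raster files are plain-text ESRI ASCII grids
  (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value), which
  round-trip values at full double precision.
* Thinning keeps the first record per cell per period — reproducible
  without a seed; the thinning grid is anchored at the raster origin.
* Variable clustering uses average linkage (UPGMA) on 1 − |r|, cut at
  1 − r_threshold; one variable per cluster, preferring a user-supplied
  biology-driven list, else maximal variance. Average linkage does not
  guarantee all kept pairs satisfy |r| < threshold; violations are
  reported, and the subsequent VIF pass (threshold 5, largest-VIF-first
  removal, singular fits treated as VIF = ∞) handles residual
  collinearity.
* Pseudoabsence count is a free parameter and defaults to the number of
  presences; the fossil-record external AUC uses a fresh 20% background
  sample in the target scenario as contrast, since an independent
  validation set supplies presences only.
* Bootstrap splits are stratified by label so both classes appear in
  every test set; 20 iterations at 40% test by default.
* Stage seeds derive from the master seed and a stage label
  (`masterSeed * 7919 + hash(label) mod 2³¹`), logged per stage, so any
  stage replays in isolation and whole runs are byte-reproducible.
* Problem sizes used in the shipped tests: climate grids of 120 × 120
  cells (the generator default) for calibration experiments, 40–60
  squared for plumbing tests; 404 presences for SDM recovery;
  100-replicate randomization tests repeated over 200 trials for
  calibration checks and 20 seeded trials for recovery contrasts.

## Known limitations

* The equivalency test's sensitivity across scenarios (above) means
  "non-equivalent" should not be read as "not conserved" without the
  similarity and dynamics evidence.
* Kernel-density occupancy depends on the bandwidth rule; the
  normal-reference rule oversmooths strongly multimodal niches. The
  resolution-doubling stability property (D moves < 0.02 when R
  doubles) is tested, but bandwidth sensitivity is the user's to
  explore.
* The Maxent-style model is a penalized Gibbs density with the stated
  feature classes, not a re-implementation of the Maxent program;
  agreement is structural (objective, regularization, gain), not
  bit-level.
* With very small fossil sets (< 10 presences) the penalized fit warns:
  coefficients are then strongly prior-dominated, mirroring the
  instability any method has at those sample sizes.
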