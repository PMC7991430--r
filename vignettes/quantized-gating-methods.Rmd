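---
title: "Methods: weighted k-means quantization and centroid-level gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted k-means quantization and centroid-level gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcquant)
```

## The quantization model

`fcquant` treats a cytometry sample as a point set
$X = \{x_1, \dots, x_n\} \subset \mathbb{R}^d$ (n events by d channels)
and summarizes it by $k \ll n$ centroids minimizing the dimension-weighted
k-means loss

$$\operatorname*{arg\,min}_S \sum_{i=1}^{k} \sum_{x \in S_i}
  (x - \mu_i)^\top \Omega\, (x - \mu_i),$$

where $\Omega$ is diagonal with non-negative entries. The default
weighting is binary: 1 for every channel the analyst selected, 0 for the
rest. Two consequences follow and both are deliberate:

* **Assignment** ignores zero-weight channels entirely (the metric
  contracts those axes to zero), so cluster structure reflects only the
  channels of interest.
* **The centroid update** averages member events over *all* d channels,
  so unselected channels ride along in the centroids. A gate drawn on an
  unselected channel is therefore still meaningful: it sees the
  cluster-conditional mean of that channel.

Each cluster's integer weight $|S_i|$ is the number of events it
represents. Every population statistic downstream (quadrant percentages,
polygon selections, density grids) is a ratio of sums of these integer
weights, never of centroid counts. This is the core trick that makes
gating on a few hundred points faithful to the underlying events: centroid
*counts* are allocated by spatial structure, not by mass, and are
measurably biased at unequal mixing ratios (the test suite demonstrates a
weighted-vs-unweighted contrast at a 75:25 mixture), while weighted
percentages are unbiased up to quantization granularity.

The assumptions are those of any vector quantization: populations must be
separated at the scale of a cluster, since a single cluster's whole weight
falls on one side of a gate boundary. With k in the hundreds and display
transforms applied first, boundary-straddling clusters contribute errors
well below one percentage point in the regimes the tests cover.

## Fitting: Lloyd's algorithm, k-means++, determinism

The fit uses Lloyd's alternating assignment/update iterations with
k-means++ initialization under the $\Omega$-metric (first centroid uniform
over events, subsequent ones drawn proportional to the squared weighted
distance to the nearest chosen centroid). All randomness flows through an
explicit integer seed (default 0, chosen for reproducibility); the RNG
state of the caller is saved and restored, and identical inputs plus seed
reproduce the fit bit-for-bit. With `restarts = r` the fits use seeds
`seed, seed+1, ..., seed+r-1` and the lowest loss wins; the default is a
single restart, which keeps the default run cheap — the restart knob
exists for small-k runs where k-means++ variance is visible.

Numerical and degenerate-case choices:

* **Convergence.** Iterations stop at label stability (an exact fixed
  point: centroids are the member means and every event sits in its
  nearest cell), with a relative loss-change tolerance of `tol = 1e-6`
  triggering a bounded polish phase (at most 50 extra iterations), and a
  hard cap of `max_iter = 300`. On return the fixed-point invariants hold
  to machine precision on all tested data.
* **Ties** in assignment break toward the lowest centroid index, making
  the partition a deterministic function of the centroids.
* **Empty clusters** (possible mid-run) are reseeded to the event farthest
  from its current centroid in the weighted metric, so every returned
  cluster has weight at least 1 and weights always sum to exactly n.
* **Loss bookkeeping.** The reported loss, the diagnostics'
  `total_variance`, and `weighted_loss()` all flow through one per-cluster
  summation helper, so `total_variance == loss` holds exactly (`==`), not
  just to tolerance. Distance matrices use the expanded-square form with
  negative clamping.

The automatic cluster count is `min(n, clamp(round(n/200), 250, 5000))`.
The clamp range is the documented automatic operating range; the
interpolation rule (one cluster per ~200 events) is this package's own
choice of how to move through that range, selected so that desk-scale
files (50k events) sit at the lower bound and million-event files at the
upper. It is monotone in n by construction.

## Display transforms

Raw cytometry values (including negatives, from compensation or baseline
subtraction) are mapped to a normalized display scale before clustering.
The package implements the GatingML 2.0 parameterizations of **logicle**
(Parks–Moore biexponential) and **hyperlog** (log-linear hybrid), plus the
identity. Parameters, all user-settable: top of scale `T` (data units,
default 262144), decades `M` (default 4.5), linearization width `W`
(decades, default 0.5), extra negative decades `A` (default 0) — the
community-standard defaults. Admissibility is enforced as `W ≤ M/2`,
`0 ≤ A ≤ W`.

Both transforms have analytic *inverses* (display → data); the forward
direction is solved by a vectorized safeguarded Newton iteration with
per-element bisection brackets, converging to ~1e-15 relative. The test
suite checks the forward solver against an independent plain-bisection
oracle, strict monotonicity, the exact anchor `transform(T) = 1`, and
round-trip identity (1e-6 relative above |x| = 1, 1e-3 absolute below).
For hyperlog the linear term's slope is matched to the exponential at the
end of the linear region (`c_a = e^{b x_0}/x_0`), which requires
`W > 0` or `A > 0`; the degenerate all-log case is rejected with a
parameter error. By default the pipeline transforms the selected
fluorescence channels and leaves scatter channels linear, but any channel
set can be transformed.

## Fidelity diagnostics

The Voronoi partition of the centroids (nearest-centroid labels under the
same $\Omega$) is by construction identical to the converged fit's labels.
Per-cluster fidelity is the **MSE** of each cell — the within-cluster
variance with the centroid as mean. Two aggregations are exposed, because
either can be wanted of an elbow plot: `total_variance` (the plain sum,
exactly the loss) and `average_mse` (mean of per-cluster means). Elbow
curves recompute the fit independently per k with matched seeds; rows are
independent, so any parallel scheme gives identical results.

Quartiles in `summary_stats()` use linear interpolation (R's default
quantile type), and correlations involving a zero-variance channel are
reported as 0 rather than NA so tables always render.

## Gating conventions

* Quadrant layout is fixed: Q1 upper-left, Q2 upper-right, Q3 lower-right,
  Q4 lower-left, matching the common annexin/viability reading (early
  apoptotic upper-left, double-positive upper-right, live lower-left).
* A coordinate exactly equal to its threshold counts as **positive**
  (upper/right). Some packages use the opposite convention; one had to be
  fixed, and "≥ threshold is positive" matches the intuition that a
  threshold names the first included value.
* Polygon gates use the even-odd rule with the boundary counting inside,
  on the vertices exactly as given (≥ 3, non-collinear, no auto-closing
  beyond the implicit last-to-first edge).
* The deep-gating stack narrows the current population cluster-wise;
  weights are never modified, so a reset is trivially lossless. Events
  inherit membership through their labels only at export time.
* Quadrant percentages are derived from integer weights; the four weights
  sum to the parent weight exactly (integer identity), and their
  percentage sum equals 100 to machine precision.

## Persistence

Quantized runs are stored in a single-file SQLite database (tables
`meta`, `clusters`, `events`, `gates`, `ranges`), REAL columns being
8-byte IEEE doubles so centroids round-trip losslessly; scalar metadata is
JSON-encoded at 17 significant digits for the same reason. A schema
version is checked on load. Gated sub-populations export as CSV (an open
format any spreadsheet loads) or FCS 3.1.

## The synthetic generators, and what the tests do not show

Three generators define the package's study conditions:

* `make_spiral(n = 5000)`: two interleaved Archimedean arms
  (`r = 1 + θ`, `θ ∈ [0, 3π]`, second arm rotated π, noise sd 0.25) — a
  worst case for centroid summarization (no Gaussian structure).
* `make_bimodal(n = 10000, sep = 6)`: two equal Gaussian modes.
* `make_mixture()`: a two-population fluorescence mixture emulating a
  WT / GFP+ mixing design. Fluorescence is log-normal (strictly positive,
  right-skewed, as typical of cytometry), with population medians 150 and
  15000 a.u. — a 100-fold separation so a midpoint gate is unambiguous;
  scatter is Gaussian near 5×10^4 a.u. Population counts are allocated
  **exactly** (`round(ratio_a · n)`), not binomially, so ratio-recovery
  checks carry no generation-level variance, and ground-truth labels are
  returned for exact truth percentages.

These emulate the geometry of real data, not its artifacts: no spectral
spillover, doublets, debris, time drift, or detector saturation. Passing
tests therefore demonstrate the correctness of the quantization and the
weighted-gating estimator on clean, well-separated populations; they do
not certify gate placement on overlapping real-world populations, where
quantization granularity near a boundary dominates the error.

Problem sizes in the test-suite and acceptance runs — mixtures of 4k–20k
events at k = 80–250, spiral 5k and bimodal 10k at k up to 250 — were
chosen as the smallest scales at which the design's contrasts (ratio
recovery within ±2 points, fidelity trends in k, estimator bias) are
clearly resolved.

## Known limitations

* Pure-R Lloyd iterations: a 10^6-event file at k = 5000 is feasible but
  slow; the design target is interactive-scale reduced data, not
  streaming throughput.
* No compensation/spillover handling (FCS `$SPILLOVER` is parsed and
  ignored); inputs are assumed compensated upstream.
* FCS support is list-mode only, `$DATATYPE` F/D/I with uniform integer
  widths; correlated/histogram modes and FCS 2.0 writing are rejected.
* Gates are rectangles-in-spirit (quadrant regions) and polygons; no
  ellipse or spline gates, and no automated gating.
* k-means quantization itself assumes roughly isotropic local structure
  under the chosen transform; heavily elongated populations are better
  served by increasing k than by trusting per-cluster MSE alone.
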