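---
title: "RSS-based localization for node networks: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RSS-based localization for node networks: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeloc)
```

This vignette is the package's own account of the science it implements:
the RSS–distance model, the trilateration procedure, the node-selection
filters, the simulation framework used to evaluate network designs, the
numerical decisions behind each, and — importantly — what the packaged
simulations can and cannot say about real field data.

## The RSS–distance decay model

A radio pulse from an animal-borne transmitter is logged by each
detecting node with a received signal strength (RSS) in dB, reported by
typical receiver hardware in the range −30 (strong) to −120 (weak).  In
open environments a log-distance path-loss model is standard, but in
structurally complex outdoor settings (vegetation, buildings, terrain)
signal bounce and shadowing break its assumptions.  A regression-based
exponential decay toward a noise floor is a better description:

$$\mathrm{RSS}(d) = a\,e^{-S d} + K$$

* `a` (dB, > 0) — the modelled excess signal strength at distance zero
  above the asymptote; `a + K` is the zero-distance RSS.
* `S` (per metre, > 0) — the decay rate.  It is stored positive and
  applied with an explicit negative sign, so there is no sign ambiguity
  in the exponent.
* `K` (dB, < 0 for plausible telemetry data) — the horizontal asymptote:
  the level at which signals are indistinguishable from the noise floor.

`rss_decay()` estimates the parameters by nonlinear least squares via
`stats::nls()` (a Gauss–Newton fit).  Starting values come from a
closed-form self-start: `K` from the weakest observed reading (minus
1 dB), `a` from the observed range, and `S` from the slope of a
log-linearised regression of `log(RSS − K)` on distance.  The `nls`
control uses `scaleOffset = 1` so that noise-free (zero-residual)
calibration data — which the test suite uses as an exact-recovery oracle —
converges cleanly instead of tripping the relative-offset criterion.
The fit is unweighted by default: each per-node window average counts
once, regardless of how many raw detections went into it.  A `weights`
argument exposes count weighting for users who want it; with typical
per-node detection counts the two differ little, and the unweighted fit
avoids giving nearby, frequently-detecting nodes extra influence on the
far tail of the curve.

Calibration campaigns should span the full informative range of
distances.  The fit requires at least 4 observations at 2 or more
distinct distances, and readings outside the receiver's reporting range
are rejected as input errors rather than silently used.

### Inverting RSS to distance

The curve inverts in closed form, \(d = -\log((\mathrm{RSS}-K)/a)/S\),
but only on \(K < \mathrm{RSS} \le a+K\).  Degenerate readings map to
documented sentinels, never to `NaN`:

* readings stronger than the modelled zero-distance value → 0 m;
* readings within `guard_db` (default 0.5 dB) of the asymptote → a
  configurable maximum-distance sentinel (`Inf` by default).

The guard exists because a reading near the noise floor is compatible
with *any* large distance: a 0.5 dB band above `K` corresponds, under the
default curve, to everything beyond roughly 900 m, where the derivative
of the curve is a few hundredths of a dB per metre — far below the noise
level.  Such readings carry no usable distance information, and
`localize()` drops them before trilateration rather than feeding the
solver a huge, essentially arbitrary range.  The 0.5 dB default is a
compromise: a larger guard discards usable mid-range readings; a smaller
one admits ranges whose inferred distance swings by hundreds of metres
per fraction of a dB of noise.

## Detection processing

Stationary calibration tests trim the first and last minute of each test
window (clock alignment at the boundaries) and average each node's
readings over the remainder; averaging damps multipath outliers.  For
free-moving animals the package generalizes this to sliding windows
(default 60 s length and stride, i.e. non-overlapping minutes — a
convention, not a measurement: a 3 s pulse interval gives ~20 pulses per
window, enough to stabilize the per-node means while remaining short
relative to typical movement).  Timestamps are assumed
GPS-disciplined by the receiver hardware; no clock-drift correction is
applied.

## Filters and trilateration

Including every detecting node in a large network *degrades* location
estimates: distant nodes report near-floor RSS values whose inverted
distances are noise, and the least-squares solution drifts toward the
centroid of the participating nodes.  Two filter families address this:

* **RSS filter** — keep nodes with mean RSS strictly above a cutoff
  (readings exactly at the cutoff are excluded; "above" is read
  literally).  Simple, but near a cutoff like −95 dB it neither
  guarantees a surrounding geometry nor a minimum node count.
* **Distance filter** — find the anchor (the node with the strongest
  mean RSS, presumed nearest the transmitter) and keep all nodes within
  a radius of it, the radius expressed as a multiple of the network's
  average spacing (or given absolutely in metres, e.g. to reproduce a
  published radius).  On a uniform grid this always retains a
  surrounding neighbourhood of at least 3 nodes, so essentially no
  locations are lost.

Anchor ties are broken by smallest node id — a probability-zero event
under continuous noise, but determinism matters for reproducibility.

The retained nodes' estimated distances feed the range-residual
objective \(\sum_i (\lVert p - n_i\rVert - d_i)^2\), minimized from a
start at the anchor's coordinates.  Each iteration solves the 2×2 normal
equations of the linearised problem; a step-halving line search
guarantees the objective never increases; convergence is declared when
the step norm falls below 1 µm (tolerance `1e-6` m), with a 50-iteration
cap.  Two numerical details matter:

* **Curvature augmentation.**  Plain Gauss–Newton converges only
  linearly when the residuals at the solution are large — precisely the
  regime of noisy telemetry ranges — and on a few percent of small
  node-set solves it zigzags past the iteration cap while already
  sitting at the minimizer, which would masquerade as location loss.
  The solver therefore adds the exact second-order term of the range
  residuals to the normal equations (a full Newton step) whenever that
  matrix stays positive definite, falling back to the plain step
  otherwise.  At zero-residual solutions the two coincide, so the
  exact-recovery behaviour is unchanged; on noisy instances convergence
  is typically reached in well under ten iterations.
* **Degenerate geometry.**  Fewer than three usable nodes returns a
  `too_few_nodes` status (an expected outcome, counted as location loss
  downstream — never an exception).  An exactly collinear node set
  leaves the cross-range direction unidentified; the solve proceeds but
  the estimate is flagged `ill_conditioned`.  Coincident nodes are an
  input error.

The test suite cross-checks the solver against an independent 1 m
brute-force grid search of the same objective on randomly generated
instances whose nodes surround the source — the geometry the distance
filter produces.  That restriction is deliberate: with nodes all to one
side of the transmitter the objective can have a mirror-image local
minimum, and no local optimizer started at the anchor can promise the
global basin.  Surrounding geometry is both the well-posed regime and
the regime the method is designed to operate in.

## The simulation framework

`make_network()` builds uniform grids on a fixed square study area
(default side 1250 m): spacings of 100, 175 and 250 m give 13×13 = 169,
8×8 = 64 and 6×6 = 36 nodes.  The fixed-extent convention was chosen
over a fixed-area one because it keeps the published per-spacing node
counts of the sparser grids exact while remaining internally consistent;
the often-quoted "12.5 km²" style area figure is dimensionally
inconsistent with those counts and is not used.  The irregular layout
(`random_in_cell`) divides the same square into k×k equal cells, k the
uniform grid's side count, and places one node uniformly in each cell —
matched node count and density, degraded regularity.  One layout is
drawn per seed and held fixed across all replicates.

`generate_rss()` emulates what a field calibration data set provides,
in two modes:

* **Parametric** (the packaged stand-in): a node detects a pulse with
  probability \(p(d) = \mathrm{logistic}((d_{50} - d)/s)\) and, when it
  does, reports the decay-curve mean plus Gaussian noise (σ, clipped to
  the reporting range).  Defaults: σ = 6 dB; slope s = 150 m, chosen
  once as a realistic transition width given that real networks record
  occasional detections out to a couple of kilometres while the curve
  flattens into the noise floor near 900 m; and d₅₀ = 844.71 m —
  *calibrated*, not free: `calibrate_dropout()` solves (by deterministic
  quadrature) for the midpoint at which two thirds of node–transmitter
  pairs over the default study square are detected, the overall
  detection fraction implied by field-scale experience with dense grids.
* **Empirical**: resample an observed (distance, RSS) calibration table —
  10 m distance bins, nearest non-empty bin within ±25 m, otherwise a
  non-detection.  This mode reproduces whatever noise structure the
  table carries and is the recommended mode when a field calibration is
  available; `make_calibration_table()` writes a synthetic table so the
  mode is fully testable offline.

`run_experiment()` runs the full factorial: for each test location
(uniform over the square; default 100) and replicate (default 1000), one
RSS vector is drawn for the whole network and *every* filter is
evaluated on that same draw — a paired design, so filter contrasts are
free of between-draw noise.  Everything is deterministic given the seed.
Per-(node, draw) noise is independent: no spatially correlated
shadowing, matching the independence implicit in resampling calibration
points one at a time.

The default problem size (100 × 1000 per configuration) runs in well
under a minute per grid on a single CPU; the test suite uses the full
size for the count/loss checks and smaller paired runs (100 locations ×
50 replicates) for ordering properties, sizes chosen to keep the whole
suite comfortably fast while leaving the Monte-Carlo error far below the
tolerances being asserted.

## Evaluation conventions

`summarize_errors()` reports, per configuration and filter: the
percentage of realizations with no estimate (location loss), the mean
number of nodes *included in the trilateration* over estimable
realizations (i.e. after both the filter and the asymptote guard — the
count that describes what the solver actually used), and the mean,
median, min and max localization error.  The 95% CI of the mean error is
a cluster bootstrap over test locations (2000 resamples, seeded):
the 1000 replicates at one location share that location, so resampling
realizations independently would pretend to far more information than
the 100 locations actually carry.  Missing estimates are excluded from
the error moments and reported only through location loss; min/max are
taken over all estimable realizations.  `edge_profile()` bins
realizations by the true location's distance to the nearest side of the
network bounding box and reports per-bin mean errors — a binned
replacement for curve smoothing that supports ordering checks
(edge vs interior, filtered vs not) without stylistic choices.

## What the packaged simulations do and do not show

Under the default parametric noise the simulations reproduce the
*geometry-driven* behaviour of node-network localization:

* noise-free end-to-end localization is exact (sub-millimetre) at
  interior points, so the estimation chain itself adds no error;
* distance filters retain the expected neighbourhood sizes (≈ 5 nodes at
  a 125 m radius on the 100 m grid, ≈ 4–5 at 315 m on the 250 m grid)
  with essentially zero location loss;
* every tested filter improves median accuracy over unfiltered
  trilateration, denser grids localize better under the strictest
  distance filter, and unfiltered error grows sharply toward the network
  edge while filtering flattens that profile.

Two quantities are *noise-law sensitive* and should not be read as field
predictions.  First, absolute error magnitudes: a constant σ = 6 dB
overstates near-node RSS scatter (penalizing filtered estimates) and
understates the heavy, erratic tail of real far-distance readings
(flattering the unfiltered baseline), so the measured improvement factor
of the strictest distance filter — roughly four-fold on the 100 m grid,
around three-fold at 175 m, and near two-fold on the 250 m grid — is a
conservative compression of the several-fold improvements seen with
empirically resampled field noise.  Second, node counts at radii that
reach into the asymptote region (e.g. a 1000 m radius on the 250 m
grid): there the count is dominated by readings within a dB or two of
the noise floor, where the Gaussian stand-in's tail and a sharp 0.5 dB
guard cannot match the empirical RSS distribution; the packaged
simulation undercounts such nodes relative to field-noise-driven runs.
Both effects are properties of the stand-in noise model, not of the
estimator; users with a field calibration table should prefer the
empirical mode, which sidesteps both.

## Known limitations

* Planar (2-D) localization only; node and tag heights are ignored.
* No movement-model smoothing across windows, no RSS fingerprinting, no
  time-difference-of-arrival: the estimate for each window uses that
  window's RSS only.
* No per-node receiver-sensitivity calibration; the decay model pools
  all nodes deliberately (robustness to node failure and network
  changes) at the cost of some per-node bias.
* The parametric noise model draws independently per node and pulse;
  real shadowing is spatially and temporally correlated, which the
  empirical mode only partially recovers.
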