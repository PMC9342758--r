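---
title: "Methods: a synthetic habitat-selection study with random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic habitat-selection study with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resource-selection functions (RSFs) contrast locations an animal *used* with
locations that were *available* to it, and model the relative probability of
use as a function of habitat covariates. `selscape` reimplements, end to end,
a use-availability RSF analysis for a territorial carnivore on a five-class
landscape (forest, agriculture, grassland, open water, developed), at two
orders of selection: placement of home ranges within a study area
(second-order) and placement of locations within home ranges (third-order).
The inferential engine is a random forest rather than a linear model, because
habitat selection near habitat edges is strongly non-linear: thresholds,
plateaus, and peaks at a few hundred meters from a boundary are exactly what a
tree ensemble represents naturally.

Because the original telemetry is not public, the package is built around a
**synthetic-data module with a known truth**: a generator for categorical
landscapes and road networks, and a telemetry simulator that samples used
points from an explicit true selection function \(w(z)\). Every downstream
stage — covariates, designs, forests, partial dependence, interaction
ranking, cross-validation — can therefore be tested for *recovery of a known
truth*, not merely for running without error.

## Covariates

Nine predictors are used throughout:

* **Seven distances (m).** Euclidean distance from each raster cell center to
  the nearest cell of each habitat class and to the nearest major/minor road
  polyline. Forest uses a *signed* convention: positive outside forest
  (distance to the nearest forest cell), negative inside forest (minus the
  distance to the nearest non-forest cell), so "deep interior" and "far from
  forest" sit on one axis and edge effects appear around zero. Distances are
  center-to-center on the lattice (roads: center-to-geometry), which matches
  the 30 m processing resolution of the land-cover product being emulated and
  makes brute-force oracles exact.
* **Habitat evenness (dimensionless, [0, 1]).**
  \(HE = -\sum_i P_i \ln P_i / \ln n\) with \(n = 5\) and \(P_i\) the class
  proportions among cells whose centers fall inside a circular moving window;
  0 means a single class fills the window, 1 means all five classes share it
  equally. \(n\) is fixed at 5 (the legend), not the number of classes
  present in a particular window, so the index is comparable across windows.
  Windows are clipped at map edges rather than padded: padding would inject a
  fictitious class into \(P_i\). The reference analysis used a window radius
  equal to the mean home-range radius (6555 m on 30 m cells); that default is
  configurable, and tests use desk-scale radii because a 6555 m window holds
  ~150k cells.
* **Sex**, encoded as a 0/1 male indicator.

## Synthetic landscape and telemetry

The landscape generator draws one Gaussian noise field per class, smooths
each with a Gaussian blur (`sigma = smoothing_length / cell_size`), and
labels each cell `argmax_k (w_k + field_k)`. The weights `w_k` are calibrated
iteratively until the realized composition matches the target within 1
percentage point per class (stopping early at 0.25 points); failure after 200
iterations is an error naming the worst class. Defaults reproduce the
emulated study area: 54% forest, 35% agriculture, 4% grassland, 2% water, 5%
developed. Roads are independent jittered polylines crossing the extent —
deliberately so: road distances are then only weakly correlated with habitat
distances, which also gives the interaction-recovery tests an identifiable
signal.

Telemetry defaults mirror the emulated study: 27 individuals (14 M / 13 F),
points per individual drawn from a rounded normal with mean 258 and SD 36
(truncated at 30), a mean home-range area of 135 km² giving a 6555 m
availability radius, and isotropic location error parameterized by its mean
displacement length (default 94 m; the component SD is
\(94 / \sqrt{\pi/2}\) so the Rayleigh mean equals 94 m). Availability during
simulation is a uniform disc around each individual's center — deliberately
*not* the kernel home range, so the home-range estimator is later genuinely
estimating something. Used points come from rejection sampling with
acceptance \(w(z)/w_{max}\); because covariates are cell-wise constant,
\(w_{max}\) over the disc is computed exactly. True RSFs can be log-linear
(with optional product interaction terms and a sex offset) or hard-threshold
rules; weights are always nonnegative, and an acceptance rate below \(10^{-4}\)
is an error rather than a silent stall.

What the generator does **not** emulate: NLCD sub-classes merged into the
five types, hydrology, realistic road topology, movement autocorrelation
(points are independent draws, as the reference analysis assumes), and the
distinction between ground and aerial location error (a single isotropic
error is used). A green test therefore establishes that the *procedures*
recover known truths on plausible landscapes — not that any particular
wild population behaves this way.

## Ranges and designs

The study area is the union of equal-radius discs (buffer radius = mean
home-range radius) about all telemetry points, dissolved. With no polygon
library in the stack, the union is computed exactly: each disc's boundary
circle is reduced to its *exposed* arcs (angular intervals not covered by
neighbouring discs) and Green's theorem over those arcs gives the exact area;
rings are discretized (≥ 256 vertices per full circle) only for GeoJSON
export. Tests check this geometry against the closed-form two-disc union.

Home ranges are 95% superlevel sets of a Gaussian-kernel KDE. The bandwidth
is a two-stage direct plug-in selector (Wand–Jones family: normal-reference
start for \(\psi_8\), kernel re-estimation of \(\psi_6\) then \(\psi_4\),
then \(h = (2\sqrt{\pi}\,\psi_4 n)^{-1/5}\)), applied per coordinate to give
a diagonal bandwidth matrix. The reference analysis used the full plug-in
matrix from the `ks` package; that library is not available here, and the
diagonal selector preserves the properties the pipeline relies on (scale
equivariance, correct order of magnitude against the normal-scale rule). If
a plug-in stage degenerates the normal-scale bandwidth is used with a
warning. The isopleth threshold is found by ranking grid densities and
accumulating mass (a Riemann sum, as contouring tools do); the enclosed mass
of the returned polygon is recorded and must lie within ±0.02 of the target.
The evaluation grid spans the points ±3 bandwidth SDs, bounding truncation
error at the 95% level.

Use-availability tables pair each individual's used points with
`ratio × n_used` available points sampled uniformly from its availability
domain (the study area at second order, its home range at third order).
Available rows inherit the individual's id and sex, since sex is a predictor
and the ratio diagnostic is per individual. The ratio diagnostic fits the
reference analysis' procedure: available-point means and SDs per covariate
and individual across ratios 1, 2, 5, 10, 20, selecting the smallest ratio
whose mean and SD change by at most 5% (relative to the larger-ratio value,
with an absolute floor of 1 on the denominator to guard near-zero means)
against every larger ratio. The reference study selected 1:10 by visual
inspection; 5% is our operationalization of "stabilized".

## The forest

Trees are CART-style (Gini) classification trees grown on
without-replacement subsamples (`sample_fraction`, default 0.623 — kept
exactly as printed in the study's tuning tables, not "corrected" to the
0.632 bootstrap constant), trying `mtry` random predictors per split.
Propensity is the fraction of trees voting "used" (a tree votes its leaf
majority; ties count ½). The reference analysis used conditional-inference
forests; the procedures built on top (OOB tuning, permutation importance,
partial dependence, interaction RMSE, LOIO AUC) are model-agnostic, and a
transparent CART ensemble was preferred over reimplementing the
conditional-inference splitting machinery. This is a deliberate, documented
deviation.

Class weights are left unadjusted despite the 1:10 imbalance, and the OOB
vote threshold stays at 0.5: propensities are interpreted *relatively*, as
in any RSF, and the OOB error is used only to compare configurations. Tuning
minimizes OOB error over a grid (trees {50, 100, 200, 500}, mtry
{2, 4, 6, 8}, fraction {0.4, 0.623, 0.8} by default) under a shared seed,
breaking ties toward fewer trees, smaller mtry, then the fraction closest to
0.623. Permutation importance is the mean OOB accuracy decrease when the
focal predictor is permuted within each tree's OOB rows.

## Interpretation

**Partial dependence** forces one predictor to each of `n_grid` equally
spaced quantiles (1–99%) of its table distribution and averages predictions
over all table rows (used + available, the standard definition).

**Interaction ranking** follows the binned procedure of the reference
analysis: each variable of a pair is cut into 10 equal-frequency bins
(representative value = midpoint of the bin-edge quantiles; the paper does
not say whether bins were equal-width or equal-frequency, and quantile bins
are the reading that "divides the data"), the 100 combinations are predicted
with all other predictors at their table means (sex at its mean indicator),
and the RMSE of an additive linear fit over the 100 predictions scores the
pair. The max-drop rule retains pairs above the largest gap in the
descending RMSE sequence; all-equal scores degenerate to retaining the top
pair only. One wrinkle: a binary predictor (sex) cannot fill 10 distinct
quantile bins, so `interaction_rmse` refuses it by default, while
`rank_interactions` — which must rank all 36 pairs of 9 predictors —
represents such a variable by its distinct values. Note what max-drop does
*not* promise: when no interaction stands out, the largest gap can sit
anywhere in an essentially flat sequence, and the retained "prefix" may be
large; what matters (and what the tests check) is that retained pairs do not
*exceed* a permuted-label null.

**Projection** predicts every cell of the covariate stack; sex has no
raster, so each cell is the average of its male and female predictions.

**Validation** is leave-one-individual-out: refit on the other individuals
(same configuration, fold seed = base + index), score the held-out
individual's used *and* available rows, and report the ROC AUC
(Mann–Whitney with ties counted ½), summarized as a mean ± SE across
individuals. Scoring the held-out animal's own availability sample is the
reading that measures predictive transfer to a new individual.

## Numerical and design choices

* Coordinates: projected meters, origin at the map's lower-left corner, cell
  centers at `origin + (col + 0.5, row + 0.5) * cell_size`, 0-based grid
  indices, row 0 at the bottom. Points on the extent edge belong to the edge
  cell; points on a domain boundary count as inside.
* Rasters persist as ESRI ASCII grids with JSON sidecars, vectors as
  GeoJSON, tables as CSV, models as versioned JSON — all plain text, so a
  pipeline run is diffable and its manifest checksums are reproducible.
* All randomness funnels through one seed-scoped helper; pipeline stage
  seeds derive deterministically from a single base seed, so one integer
  reproduces an entire synthetic study. Rejection samplers fail loudly
  (acceptance < 1e-4 for used points, < 1e-6 for available points) instead
  of looping forever.
* Road distances use exact vector geometry (the alternative — rasterizing
  roads first — would quantize distances by up to half a cell diagonal; the
  reference analysis does not say which it used).
* Acceptance-scale simulations are scaled down from the field study (e.g.
  ~50 used points per individual instead of ~258 for the
  leave-one-individual-out null tests) to keep the full suite inside its
  runtime budget; the scale factors are fixed in the scenario helpers, not
  tuned.

## Known limitations

The forest is a plain CART ensemble: importances inherit the usual bias
toward predictors with many split points, which conditional-inference
forests were designed to avoid; no probability calibration is applied to
propensities; the KDE bandwidth is diagonal; the disc-union geometry assumes
equal buffer radii (which the buffer–dissolve definition guarantees); and
the pipeline assumes a single projected CRS throughout.
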