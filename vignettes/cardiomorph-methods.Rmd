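---
title: "Methods: morphometrics, protein profiling, PLSR and the Nrg1 network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometrics, protein profiling, PLSR and the Nrg1 network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the models and
procedures, the assumptions behind them, the tunable parameters and their
defaults, the numerical choices, and what the synthetic benchmarks do and
do not establish. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# Single-cell morphometrics

## The metric panel

Each segmented cell is reduced to 15 metrics: 10 size metrics (area,
perimeter, convex area, equivalent diameter, major and minor axis lengths,
bounding-box width and height, max and min Feret diameters — all in
physical units via `pixel_size`, in µm per pixel for typical microscopy)
and 5 dimensionless shape metrics (Feret elongation, eccentricity, form
factor, solidity, extent). Only a handful of these have a canonical
definition fine enough to pin down a digital implementation uniquely, so
the remaining conventions are fixed here explicitly:

- **Feret diameters** are computed on the convex hull of the *pixel
  corners* (each foreground pixel treated as a unit square), not the pixel
  centers. The max Feret diameter is the hull diameter; the min is the
  rotating-calipers width (minimum over hull edges of the farthest-vertex
  distance). Using corners means a one-pixel-wide line has min Feret = 1
  pixel rather than 0, avoiding a division-by-zero in the elongation of
  degenerate shapes.
- **Feret elongation** is `max_feret / min_feret - 1`: 0 for a circularly
  symmetric cell, √5 − 1 ≈ 1.24 for a 1:2 rectangle, growing without
  bound. It is scale- and rotation-independent, which the suite checks
  directly (size metrics scale linearly/quadratically with `pixel_size`,
  shape metrics are invariant; quarter-turn rotations change elongation by
  < 1 %).
- **Perimeter** is the crack perimeter — the total length of exposed pixel
  edges. This choice guarantees `form_factor = 4π·area/perimeter² ≤ π/4`
  for every digital region (digital isoperimetric inequality), so the
  form factor stays in (0, 1] without clamping. The cost is that even a
  perfect disk scores ≈ 0.62 rather than 1; form factor here is a
  relative roundness index, consistent across shapes, not an absolute one.
- **Axis lengths and eccentricity** come from the second central moments
  of the pixel centers plus the 1/12 per-pixel variance of a unit square.
  The correction keeps the minor axis nonzero and eccentricity strictly
  below 1 for line-like masks, matching the corner-based hull convention.
- Masks are row-major, 0-based, boolean; a mask must have exactly one
  4-connected foreground component to enter shape analysis. Empty masks
  (cells with undetectable cytoplasm) are representable but always
  rejected by the QC filter and counted as filtered.

The rotating-calipers result is checked against an independent exhaustive
projection search over caliper orientations on a 0.25° grid
(`feret_projection_search()`), agreeing within 0.5 % on seeded random
smooth-boundary masks.

## QC, summarization and profiling

Cells are retained when `integrated_intensity ≥ min_intensity` and
`pct_neighbors_touching ≤ max_pct_touching`. The criteria are fixed; the
cutoffs are not canonical, so they are configuration parameters with
permissive defaults (0 and 0.5). Wells are summarized by per-metric
medians (midpoint convention for even counts) — the median is robust to
the heavy right tail of cell-size distributions. Treatment effects are
profiled per metric as (mean of treated well medians)/(mean of control
well medians) − 1, so 0 means no change; the ratio is undefined (an error)
if a control mean is exactly zero.

# RPPA preprocessing

Raw probe × condition matrices (columns `ligand_timepoint_replicate`) are
normalized per probe to the mean control (serum-free) value at the
*matching timepoint* — loading normalization must not mix timepoints — and
then log2-transformed. States are tracked (`raw → control_normalized →
log2fc`) and each step refuses inputs in the wrong state, which catches
double-normalization bugs cheaply.

Top-responder selection takes the `ceiling(fraction × n_probes)` probes
with the largest |log2FC| in a condition, with `fraction = 0.20` by
default. Ranking by absolute change captures both up- and down-regulation,
matching a signed heatmap's notion of "most responsive"; signed ranking is
available as an option. Replicates are averaged before selection
(responses are reported at condition level), timepoints are treated as
independent conditions, and boundary ties break lexicographically by probe
id so the selection is deterministic. Venn overlaps are exclusive region
counts over 2–4 sets; the counts always sum to the union size.

# PLSR: protein signatures → phenotypes

## Model and algorithm

X (conditions × probes) and Y (conditions × outputs) are column z-scored
across conditions using the sample (n − 1) standard deviation;
zero-variance columns are dropped with a warning. Condition rows are
ligand × timepoint combinations — with 4 ligands and 2 timepoints that is
8 observation rows, which is the intended operating regime: PLSR exists
precisely to regress wide blocks on few observations. (Stacking the two
timepoints as extra *features* instead of extra rows is possible by
reshaping the input before the fit; rows-as-conditions is the default
layout.)

The fit uses SIMPLS: each component's weight vector is the dominant left
singular vector of the running cross-product matrix S = Xᶜ′Yᶜ, deflated
against an orthonormal basis of X-loadings. Scores come out orthonormal
(checked to 1e-8), and per-component explained variances for X and Y are
exact partitions of each block's sum of squares, so cumulative R² is
non-decreasing and ≤ 1 by construction. A classical NIPALS PLS2
implementation lives in the test helpers as a second-algorithm oracle; at
full rank both algorithms reproduce the same projection (prediction
agreement < 1e-6), and their leading components coincide. Components are
capped at `min(rows − 1, predictors)`; if the cross-covariance is
exhausted earlier, the model truncates with a warning rather than
fabricating components.

## Validation metrics

Q² is true leave-one-out: each condition row is left out, the model is
refit on the rest, and `Q² = 1 − PRESS/TSS` with TSS accumulated against
the training-fold means (the out-of-fold mean is the honest null
predictor). With ~8 rows the inner fits see n − 1 rows, so the component
count is capped at rows − 2. Q² ≤ R² at every component count, and the
median Q² over seeded row-permutations of Y is ≤ 0 — both are enforced as
properties of the implementation, not assumptions.

Loadings are clustered with k-means in the LV1/LV2 plane (the plotted
biplot space): k-means++ seeding followed by Lloyd iteration, fully
determined by the seed. k is a free parameter — there is no canonical
cluster count for a loading plane — and defaults to 4 in the pipeline.
Alignment of a probe with a phenotype is the cosine similarity of their
loading vectors restricted to the first two components: +1 parallel, −1
anti-parallel, 0 orthogonal. This is the natural quantitative reading of
"pointing the same way in the biplot"; negating a phenotype column negates
its alignment scores exactly.

# The Nrg1 logic-based ODE model

## Formulation

Each node i obeys

    dy_i/dt = (1/τ_i) · (Ymax_i · F_i(upstream) − y_i)

with F the gated composition of incoming reactions. A reaction applies a
normalized Hill activation to each source,

    f(x) = β xⁿ / (K^n + xⁿ),  β = (EC50ⁿ − 1)/(2·EC50ⁿ − 1),  K = (β − 1)^(1/n),

anchored so f(0) = 0, f(1) = 1, f(EC50) = 1/2 exactly (the suite checks
1e-9). The construction requires EC50ⁿ < 1/2; the constructor rejects
parameters outside that region rather than producing complex constants.
Inhibiting sources enter as 1 − f. Within a reaction, multiple sources
combine by the declared gate (AND = product for interdependent inputs);
reactions sharing a target always combine by noisy-OR,
`1 − Π(1 − w_r·g_r)` — the standard continuous-logic convention for this
model family, associative with identity 0. Defaults: W = 1, EC50 = 0.5,
n = 1.223, τ = 0.1, Yinit = 0, Ymax = 1.

Nodes with no incoming reactions follow their piecewise-constant input
schedule algebraically (they are inputs, not states). This makes the
documented single-node steady state exact: a node driven by constant input
u through a weight-1 reaction settles at `Ymax · f(u)`, verified against
the closed form at five inputs to 1e-6.

## Topology and time constants

The built-in network is the minimal text-consistent topology: Nrg1 → ERBB;
ERBB → PI3K → Akt → {Elongation, Area}; ERBB → Ras; (Ras AND NOT DUSP) →
p38; p38 → {Area, DUSP}. Area is therefore a noisy-OR of the Akt and p38
branches, and DUSP closes the negative feedback that makes p38 transient.
Elongation and Area are identity readouts (no separate downstream
transform); they are reported as steady-state activities.

Per-node time constants are not individually published, so the package
fixes a two-scale default — τ = 0.1 for receptor-proximal nodes (ERBB,
Ras, p38) and τ = 1.0 for PI3K, Akt, DUSP and the phenotype nodes —
chosen once to reproduce the qualitative experimental signature (early
transient p38, slowly rising Akt) and exposed via `tau_overrides` for
recalibration. Under the treatment step (Nrg1 input weight 0.02 → 0.3 at
t = 0) this yields a p38 peak at an interior time with final/peak < 0.9
and an Akt half-max time later than the p38 peak; ablating the DUSP edge
makes p38 monotone, confirming the feedback is what produces the
transient.

Kinase inhibitors are modeled as `ymax_scale = 0` on the targeted node
(PI3K for LY294002-like, p38 for SB203580-like); partial inhibition is the
same mechanism with factor ∈ (0, 1), and `weight_scale` offers the
alternative of attenuating incoming reactions instead.

## Numerics

Integration uses deSolve's `lsoda` (stiff-capable, adaptive) with
rtol = 1e-8, atol = 1e-10 and 200 uniform output times over t_end = 20
dimensionless time units, restarting the integrator at schedule
breakpoints so step inputs are sharp rather than smeared. Activities
remain in [0, Ymax] by the structure of the dynamics (F ∈ [0, 1]); the
suite verifies boundedness to 1e-6 and cross-checks full-network
trajectories against an independent fixed-step RK4 integrator
(dt = 1e-3) to 1e-4 max-norm. Specs round-trip losslessly through a JSON
schema and can also be written in a terse reaction grammar
(`!DUSP & Ras => p38`).

# Synthetic data: what it emulates, and what it does not

The generators are the package's test bed and define its study
conditions:

- **Masks** are rasterized disks, ellipses, rectangles and smooth random
  blobs (radial Fourier perturbation of a disk) with closed-form area and
  Feret elongation where the shape admits one. They emulate segmented
  cardiomyocyte silhouettes of controlled aspect ratio; they contain no
  segmentation errors, holes, or touching-cell artifacts, so passing
  geometry tests says the *metrics* are right, not that segmentation
  noise is handled.
- **Omics blocks** copy the study design (172 probes × 4 ligands × 2
  timepoints, 15 outputs) with 2 planted latent factors, unit-norm probe
  loadings, decaying factor scales and Gaussian noise (σ = 0.05 by
  default). The bilinear-plus-noise form deliberately mirrors the PLSR
  model's own assumptions so that subspace recovery (principal angles
  < 10° to the planted loadings) is a well-posed test of the fitting
  code — it is a statement about the implementation, not about real RPPA
  noise, which has probe-specific, non-Gaussian structure. Recovery is
  assessed on centered, unscaled blocks: column z-scoring rescales the
  planted loading directions (a change of basis), so the angle is
  measured in the frame where the truth is defined.
- **Phenotype wells** plant per-metric relative shifts with Gaussian
  well-to-well noise (CV 0.05), sized so a null effect reads as 0 within
  ~3 standard errors at 50 wells and a +50 % area shift is recovered by
  `fold_change_profile()`.

All generators are pure functions of (config, seed); every generated
artifact passes its consuming module's validation unmodified.

# Problem sizes and runtime choices

The default test and pipeline scales — 30-cell wells at 25 px
characteristic size, 172 × 8 omics blocks, 20-mask geometry batches,
t_end = 20 network runs — were chosen as the smallest sizes at which each
property is cleanly identifiable (rasterization error well under the 2 %
elongation tolerance, latent factors well above noise, steady states
reached to 1e-4). The full suite runs in well under a minute on one core.

# Known limitations

- The 15-metric panel fixes the unnamed members of the size/shape split
  by convention; other region-property sets are defensible.
- Crack perimeter biases form factor low for smooth shapes (consistent,
  but not comparable to contour-integral perimeters from other tools).
- The network's time constants are a qualitative calibration, not a fit
  to time-course data; absolute times in the simulation are
  dimensionless.
- PLSR with 8 condition rows cannot support more than ~6 components and
  Q² estimates at that n are high-variance; the permutation null is the
  guard against over-reading them.
- The pipeline's RPPA stage embeds known fold-changes into a synthetic
  raw matrix; real matrices enter through `read_response_matrix()` and
  skip that stage.
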