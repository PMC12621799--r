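# cardiomorph

Cardiomyocytes grow in two distinct modes: they thicken (concentric
hypertrophy) or they lengthen (eccentric hypertrophy, the mode seen after
volume overload or endurance exercise). Neuregulin-1 (Nrg1) is a potent
inducer of cardiomyocyte elongation, and dissecting which signaling
branches drive elongation versus overall cell area requires a chain of
quantitative methods: single-cell shape measurement, protein response
profiling, regression from signaling state to phenotype, and a dynamic
network model that can be perturbed in silico. `cardiomorph` implements
that chain end to end, with synthetic-data generators of known ground
truth so every stage is testable on a laptop with no external data.

The package is aimed at quantitative cell biologists and systems
biologists working on hypertrophic signaling, and more generally at anyone
who needs Feret-based shape metrics, RPPA-style preprocessing, SIMPLS
regression with leave-one-out Q², or logic-based ODE signaling models in R.

## What it computes

**Morphometrics.** From a binary segmentation mask, 15 per-cell metrics
(10 size, 5 shape). The headline shape metric is *Feret elongation*,

```
Feret elongation = max Feret diameter / min Feret diameter - 1,
```

where the Feret diameters are the extreme caliper distances of the cell
over all orientations, computed by rotating calipers on the convex hull of
the pixel corners. It is 0 for a perfectly non-elongated (circularly
symmetric) cell, scale-independent and rotation-independent. Cells are
QC-filtered on integrated intensity and neighbor contact, wells are
summarized by per-metric medians, and treatments are profiled as
fold-change from control minus 1.

**RPPA preprocessing.** Probe × condition matrices are normalized per
probe to the mean serum-free control at the matching timepoint,
log2-transformed, replicate-averaged, ranked by |log2 fold-change| to
select the top 20 % responders per ligand, and compared across ligands by
exclusive Venn region counts.

**PLSR.** A SIMPLS partial least squares regression maps the z-scored
protein block X (conditions × probes) to the phenotype block Y
(conditions × outputs), maximizing predictor–response covariance per
latent component. Performance is tracked as cumulative R² and
leave-one-out Q² = 1 − PRESS/TSS; protein loadings are k-means-clustered
in the LV1/LV2 plane and scored for alignment (cosine similarity) with
phenotype loadings.

**Logic-based ODE network.** Each node follows
`dy/dt = (1/τ) (Ymax · F(upstream) − y)` where `F` composes normalized
Hill activations `f(x) = β xⁿ / (K^n + x^n)` (anchored so f(0)=0, f(1)=1,
f(EC50)=0.5; defaults W = 1, EC50 = 0.5, n = 1.223, τ = 0.1, Yinit = 0,
Ymax = 1) through continuous AND (product) and OR (noisy-OR) gates,
inhibitors entering as 1 − f. The built-in Nrg1 network (Nrg1 → ERBB →
{PI3K → Akt → elongation/area} and {Ras → p38 → area} with p38 → DUSP ⊣
p38 feedback) reproduces the transient p38 / slowly rising Akt signature
under the 0.02 → 0.3 input step, and supports in-silico kinase inhibition
via Ymax or reaction-weight scaling.

## Worked example

The `analysis/` directory holds the numbered study drivers
(`01_simulate.R` … `05_network.R`); each writes its tables under
`results/`. Running them in order prints, among other things:

```
masks: 180 cells; true elongation 0.2 / 1
retained 180 cells; median elongation control 0.202 vs treated 0.982
fold-change-minus-1: feret_elongation +3.755, area +0.665
top 20% per ligand: 35 probes each
Venn: shared by all four = 0 | union = 79
2 LVs explain 99.9% of phenotype variance; LOO Q2 = 0.998
per-output R2: area 0.999, feret_elongation 0.999
p38 peaks at t = 0.80 (final/peak 0.89); Akt half-max at t = 1.91
 condition steady_state.Elongation steady_state.Area
      base                0.229839         0.3736046
     PI3Ki                0.000000         0.1866696
      p38i                0.229839         0.2298390
```

Reading these: the synthetic "treated" cells were planted with true Feret
elongation 1.0 versus 0.2 in controls, and the measured well medians
(0.982 vs 0.202) recover that within rasterization error. On the omics
side the two planted latent factors carry essentially all the variance, so
the 2-component model reaches Q² ≈ 1 — by construction, not as a claim
about real RPPA data. In the network, p38 peaks early and decays below
90 % of its peak (DUSP feedback) while Akt reaches half-maximum later;
knocking out PI3K (Ymax = 0) lowers both elongation and area steady
states, while knocking out p38 lowers area only — the differential pathway
dissection the model was built to formalize.

The same chain runs as one call from a single config via
`run_pipeline(pipeline_config(), "results")`, which also writes an MD5
manifest: identical configs reproduce identical hashes.

A quick interactive taste:

```r
library(cardiomorph)
disk <- gen_cell_masks(shape_config("disk", size_px = 100), 1)$masks[[1]]
compute_features(disk)$feret_elongation   # ~0.007, i.e. 0 within raster error
normalized_hill(0.5, hill_params())       # exactly 0.5 at the EC50
```

## Documentation

Every exported function carries roxygen documentation, and the methods
vignette (`vignettes/cardiomorph-methods.Rmd`) describes the models, their
assumptions, parameter defaults, numerical choices, and what the synthetic
benchmarks do and do not establish about real data.
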