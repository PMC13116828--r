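---
title: "eamrisk: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eamrisk: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamrisk)
```

## Overview

`eamrisk` turns per-point left-ventricular electroanatomic-mapping exports
into spatially normalized substrate features and models the risk of major
arrhythmic events (MAE) from those features together with clinical
covariates. This vignette documents the method as implemented: the
normalization and feature definitions, every tunable that matters, what the
synthetic-data generator does and does not emulate, the numerical
conventions, and the design decisions that were genuinely open.

## Spatial normalization

**Canonical frame.** Mapping coordinates arrive in an arbitrary patient/
system frame. `canonical_orientation()` centres the cloud on its centroid
and rotates the principal axes of the position covariance onto a canonical
frame: largest-variance axis to z, second to x, third to y. The rotation is
always proper (determinant +1); the third axis is constructed as z × x, so a
reflection can never be introduced. Eigenvector signs are fixed by the data:
+z is oriented so the projection of the cloud on it correlates positively
with activation time (the apico-basal direction carries the dominant
activation trend, so +z acts as an apex proxy), and +x so it correlates
positively with unipolar voltage. If a channel is exactly constant the sign
falls back to making the axis's largest-magnitude component positive. These
conventions are deterministic and make canonical forms of rotated/translated
copies of one cloud identical to numerical precision (tested at 1e-6).

**Size.** The cloud is rescaled so its RMS distance from the centroid equals
`reference_rms` (default 30 mm, a typical mapped LV scale). Normalizing size
is part of the stated goal — hearts of different sizes must become
comparable — and it is what makes the *entire* feature vector, including the
distance-based activation gradient, invariant to uniform rescaling of the
input coordinates. The cost is that gradients are expressed in normalized
millimetres; for a heart whose RMS radius is exactly 30 mm they coincide
with raw mm.

**Tessellation.** The reference sphere is cut into `n_bands` = 120 bands of
uniform height in z and `n_lon` = 120 longitude sectors. By Archimedes'
hat-box theorem every cell has area 4πR²/14,400 *exactly*, so the equal-area
requirement holds to machine precision rather than approximately; cell
lookup from a direction is O(1) arithmetic. The alternative — irregular
polyhedral tessellations — offers more isotropic cells but only approximate
area equality and slower lookup; exactness and speed won. Cells near the
poles are elongated in latitude; none of the implemented features depends on
cell shape, only on cell area and the adjacency metric.

**Projection.** Points project radially from the centroid onto the sphere;
each lands in the face containing its direction. The face count is chosen so
that a clinical-scale map (~1,500 points) almost never puts two points in
one face; when it happens the point whose direction is closest to the face
centre is kept, a warning reports the collision count, and the count is
returned in the diagnostics. For 1,500 uniform points the expected number of
collisions is about n²/(2·14,400) ≈ 78, i.e. ~5% of points, which perturbs
extent denominators by a comparable relative amount (see *Recovery
tolerances* below).

**Regions.** The 8 anatomical regions are the octants of the canonical
frame, each 1,800 faces. Band and sector midpoints never lie on a
coordinate plane, so the assignment is unambiguous. The octant → label map
is a fixed, configurable convention (`default_region_map()`); no image
registration is performed, and the anatomical names are nominal labels for
geometric octants.

## Substrate features

All thresholds of the "extreme 20% of the range" type use strict
inequalities, so a degenerate channel (zero range) yields an empty critical
set and a 0% extent rather than flagging everything.

**Activation gradient (GR).** Per point: the maximum of |ΔLAT|/distance over
neighbours within `gr_radius` (default 7 mm in normalized coordinates, the
scale of clinically described deceleration zones). Pairs closer than
`gr_min_dist` = 0.1 mm are skipped, never divided by. A point with no
admissible neighbour gets 0. The scalar summary is the `gr_prob` = 0.95
quantile of per-point values — the maximum is a single-pair statistic and
too fragile; the regional value is the regional maximum, because an isthmus
is a local extreme, not an average property. Both are configurable.

**Clustering.** Critical faces are grouped into connected components under
the face-grid metric (bands + wrapped sectors); two faces link when their
grid distance is at most `link_radius`, and components with at least
`min_cluster` = 3 faces count as an "area". Strict edge adjacency
(`link_radius` = 1) is degenerate at clinical density: with 1,500 points on
14,400 faces occupancy is ~10%, adjacent occupied pairs are rare, and every
clustered extent collapses toward zero. The default `link_radius` = 4 comes
from the isolation probability exp(−ρ·2r(r+1)) at design density ρ ≈ 0.104:
the expected inter-point spacing is √(14,400/1,500) ≈ 3.1 cells and r = 4 is
the smallest radius that drops the isolated-face rate below ~2%, so
contiguous substrate forms single clusters while well-separated points do
not chain.

**Voltage discrepancy (VLT).** Per occupied face d = bipolar − unipolar
voltage; faces in the upper `tail_frac` = 20% of the range of d are
critical; critical clusters ≥ `min_cluster` count; extent = counted faces /
occupied faces × 100. The *signed* difference is the default on physical
grounds: healthy tissue has unipolar ≫ bipolar (d ≈ −5 mV at the generator's
baselines), and the substrate this parameter is meant to flag — unipolar
depression with preserved bipolar voltage, i.e. intramural/deep substrate —
moves d toward zero or positive, into the upper tail. An absolute-value
variant (`vlt_measure = "abs"`) is provided, but note that under realistic
amplitudes a unipolar depression can only *shrink* |d|, so the upper tail of
|d| selects the healthiest tissue instead.

**Late-potential extent (LAT).** Late faces are those in the *latest*
`tail_frac` = 20% of the activation-time range (configurable to earliest:
the clinical term "late potential" fixes the direction used as default).
The extent denominator is the set of non-late occupied faces — the
percentage-of-non-late-potentials convention — and can therefore exceed
100; `late_denominator = "total"` switches to all occupied faces.

**Scar areas.** Occupied faces with bipolar voltage < `scar_cutoff` = 0.5 mV
(the conventional dense-scar threshold), clustered as above, as % of
occupied faces.

**Regional impedance.** Mean impedance of occupied faces per region; empty
regions propagate NA.

Features needing at least two occupied faces return NA with a warning below
that. The 44-column feature vector (4 scalars + 5 × 8 regionals) has stable
names (`feature_names()`).

## The synthetic generator

`substrate_scenario()` + `generate_map()` emulate what the pipeline needs to
be testable, not electrophysiology:

- Points are sampled area-uniformly (rejection sampling against the surface
  element) on an ellipsoidal shell and jittered radially (SD 1 mm). The
  default semi-axes are 40/32/26 mm with the long axis on z and the middle
  axis on x — i.e. the generation frame *is* the canonical frame. The
  transverse axes are deliberately distinct: with two equal semi-axes the
  principal-axis frame is ill-posed (the transverse eigenvectors are an
  arbitrary basis of a degenerate eigenspace) and no deterministic
  orientation can exist.
- Channel baselines: unipolar 8 mV with a +0.03 mV/mm trend along x,
  bipolar 3 mV, activation −20 ms with a +0.3 ms/mm apico-basal slope along
  z, impedance 100 Ω; independent Gaussian noise per channel (defaults 0.5 /
  0.3 mV, 3 ms, 5 Ω). The two spatial trends are mild, physiologically
  sensible, and serve a structural purpose: they pin the canonical-frame
  sign conventions so every generated patient lands in the same anatomical
  frame. Setting them to zero (as the degenerate-input tests do) makes the
  sign fall back to the component convention.
- Patches are geodesic caps around the centroid direction of a target
  region; effects compose additively (scar: bipolar shifted so the patch
  mean becomes the configured value; late: LAT offset; VLT: unipolar
  depression). The isthmus is a linear activation ramp of height `step_ms`
  over `width_mm`, confined to a 22° cap at the region centroid — 22° keeps
  the ramp ≥ ~7 mm clear of the octant border, so the steep gradient (and
  the 7 mm GR neighbourhoods that straddle it) stays inside the target
  region.
- The generator records per-point ground-truth masks in the `planted`
  attribute for validation studies.

What it does **not** emulate: electrogram morphology (fragmentation is not
algorithmizable from amplitude surrogates and is out of scope), catheter
contact physics, spatially correlated noise, non-convex chamber shapes
(aneurysms) and mapping-density bias toward regions of interest. Passing
tests therefore demonstrate correctness of the *computational* pipeline and
recoverability of planted effects — not clinical validity on real maps.

`generate_clinical()` draws a 21-variable covariate table (symptom class,
echo, labs, comorbidities, history flags) from documented distributions
(NYHA uniform 1–4; continuous truncated normals, e.g. systolic pulmonary
pressure mean 30 SD 8 truncated ≥ 10; binaries at stated prevalences),
optionally with MCAR missingness. With `include_features = TRUE` the
substrate scalars GR/LAT/VLT/ScarAreas are drawn directly (truncated
normals: GR mean 2 SD 1, LAT mean 30 SD 15, VLT mean 20 SD 10, Scar mean 15
SD 10, all ≥ 0) for modelling studies that bypass map generation; in the
full pipeline (`run_pipeline()`) these columns come from extracted features
instead, closing the loop.

`outcome_model()` holds the generative logistic polynomial; the default —
intercept −21.007, NYHA 3.889, PAP 0.262, LAT 0.034, GR 0.492, Hypertension
2.638 — is the package's reference clinical risk polynomial and gives an
event rate near 50% under the default covariate distributions, which is the
most informative regime for simulation-and-refit experiments (the
acceptance script recovers all coefficients within 3 standard errors at
n = 20,000).

## Risk modelling

- **Split.** Stratified 80:20 with largest-remainder allocation (the split
  sizes are exact, not rounded per stratum), then 3 stratified folds inside
  the training set. The test set is used exactly once, for final metrics.
- **Screening** is outcome-blind and attributes each dropped column to
  exactly one rule, in the precedence operator-dependent → missingness
  (< 10% non-missing, a deliberately permissive literal cut) → constant →
  low heterogeneity (< 5% of values differ from the mode, where
  "differing" is measured against the modal value). **Imputation** is
  median/mode, fitted on training rows only when a split is supplied.
- **Families.** `logistic` (ML via `glm`; the binary outcome makes logistic
  the faithful reading of "linear regression" for this task, and a literal
  linear-probability variant `linear` is kept), `linear-svm` and `rbf-svm`
  (`e1071`, Platt-scaled probabilities; the RBF γ defaults to 1/p), `ann`
  (`nnet`, one hidden layer, default 16 units, weight decay 1e-3, fixed
  seed; 0 hidden units with skip connections reproduces logistic
  regression, which the tests exploit as a nested-model check). Predictors
  are standardized internally; linear families report coefficients mapped
  back to the original scale.
- **Separation.** Small cohorts with strong predictors separate; ML
  coefficients then diverge. When a standardized coefficient exceeds 15 (or
  `glm` fails to converge) the fit falls back, with a warning, to a lightly
  L2-penalized logistic likelihood (λ = 0.01 on standardized coefficients,
  intercept unpenalized) optimized directly — coefficients stay bounded and
  probabilities finite. Runaway coefficients are a symptom worth surfacing,
  not reproducing.
- **Metrics.** AUC is the Wilcoxon rank statistic (ties at ½); threshold
  metrics use probability 0.5. Single-class evaluation sets yield NA AUC;
  an empty positive-prediction set yields NA precision.
- **Search.** Candidates are pre-ranked by univariate training AUC, the top
  `pool_size` (default 20) form the pool, and all subsets up to `max_vars`
  (default 8) are scored by mean cross-validated AUC with ties broken by CV
  accuracy, then fewer variables, then a lexicographic key (full
  determinism). The top `top_k` = 6 subsets are refitted on the whole
  training set and reported with train/test metrics plus a
  frequency-of-occurrence table. Exhaustive enumeration over a ranked pool
  is a transparent surrogate for an unspecified search heuristic; the guard
  `max_subsets` keeps it desk-scale.
- **Shapley attribution.** The coalition value v(S) mixes the explained
  instance (features in S) with background rows (features not in S),
  averaging predictions over the background. Up to 10 features all 2^p
  coalitions are enumerated — exact values, efficiency holds to machine
  precision. Beyond that, permutation sampling: each sampled permutation
  contributes telescoping marginal gains against one sampled background row,
  so efficiency holds by construction and the estimate is unbiased; its
  Monte-Carlo error scales as 1/√n_samples (default 200).

## Numerical conventions and degenerate inputs

- Points coinciding with the centroid (norm < 1e-9) are dropped with a
  warning; an all-coincident cloud is an error. Rank-deficient clouds
  (minimum eigenvalue ≤ 1e-10 of the maximum) cannot be oriented: error.
- Collision tie-break: largest direction·face-centre dot product, then
  first point in acquisition order.
- Quantiles use R's default type 7; cluster ids are assigned in
  first-appearance order; subset ranking uses a full deterministic key.
- The pipeline derives per-stage seeds as (seed·101 + offset) mod 2³¹−1
  with fixed per-stage offsets, so stages are independently reproducible
  from one global seed.

## Recovery tolerances

The planted-scar recovery test compares the scar extent against two ground
truths. At *face level* — occupied faces whose surviving source point lies
in the planted cap, clustered with the same rule by an independent
flood-fill — agreement must be exact: the voltage pathway must reproduce
the planted geometry face for face. At *point level* the extent differs
from the planted point fraction by discretization: projection collisions
(~n²/28,800 faces lost, ~5% at n = 1,500) and isolated critical faces
dropped by the min-cluster rule (~2% at `link_radius` = 4). Both effects
are O(1 percentage point) for a ~6–10% planted fraction, so the point-level
tolerance is fixed at 1.5 percentage points from this analysis. A
hypothetical exact point-level equality would require either a collision
rule that never discards points or clustering without a minimum size; both
contradict the method's stated definitions.

## Problem sizes in the test suite

Tests run desk-scale by choice: oracle-equivalence sweeps use 50 random
maps of 100–400 points against brute-force recomputation; invariance uses
20 random rigid motions of a 400-point map; recovery uses 1,500-point maps
(3 scar seeds, 20 isthmus seeds); coefficient recovery uses one
20,000-patient simulation; the model-search check uses a 300-patient cohort
with a pool of 10 candidates. These sizes make every property decidable in
seconds to a couple of minutes while remaining at or above the densities
the method is designed for.

## Known limitations

- Regions are geometric octants with anatomical names; real anatomical
  correspondence would need registration to imaging, which is out of scope.
- The LAT extent can exceed 100% under its literal non-late denominator.
- The 10%-non-missing screening cut is unusually permissive; it is applied
  literally and deliberately.
- Univariate pre-ranking can exclude variables that are informative only in
  combination; enlarge `pool_size` where that matters.
- SVM probabilities are Platt-calibrated on the training fit and can be
  optimistic on tiny folds.
- Synthetic channels are statistical surrogates; no conclusion about
  predictive performance on real cohorts should be drawn from synthetic
  metrics.
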