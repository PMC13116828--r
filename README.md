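# eamrisk

Spatially normalized substrate analysis of left-ventricular electroanatomic
maps (EAM) and predictive modelling of major arrhythmic events (MAE).

## The problem

Catheter-based electroanatomic mapping produces, for each patient, a cloud of
endocardial points carrying position (mm), catheter-orientation angles,
unipolar and bipolar electrogram voltage (mV), local activation time (LAT,
ms) and impedance (Ω). Hearts differ in size, position and orientation, so
per-point values from different patients are not directly comparable, and the
prognostically interesting quantities are not the raw values but derived
*substrate* parameters: where conduction decelerates, where late potentials
cluster, where bipolar voltage collapses while unipolar voltage survives, and
where dense scar sits.

`eamrisk` implements that analysis end to end, for electrophysiologists and
biostatisticians studying arrhythmic-risk stratification:

1. **Spatial normalization.** Each point cloud is centred on its centroid,
   rotated into a canonical principal-axis frame (long axis → z, with
   data-driven deterministic sign conventions) and rescaled to a reference
   RMS radius, then projected radially onto a fixed sphere whose surface is
   divided into **14,400 equal-area faces** (120 z-uniform bands × 120
   longitude sectors; equal area is exact by Archimedes' hat-box theorem).
   Each face holds at most one projected point. The sphere is partitioned
   into **8 regions** with anatomical labels (anterior sub-mitral,
   postero-septal mid-apical, ...), so every point maps to a cardiac region.

2. **Substrate features.** From the projected map, globally and per region:
   - **GR** — activation gradient: per point, max over neighbours within a
     radius *r* of |ΔLAT|/distance (ms/mm); scalar summary is the 95th
     percentile, regional value the regional maximum. High GR marks
     deceleration zones and candidate isthmuses.
   - **VLT** — voltage-discrepancy extent: faces in the upper 20% of the
     range of (bipolar − unipolar) voltage, clustered by face proximity;
     extent as % of occupied faces. Flags unipolar depression with preserved
     bipolar voltage (intramural substrate).
   - **LAT** — late-potential extent: faces in the latest 20% of the
     activation-time range, clustered; extent as % of non-late faces.
   - **Scar Areas** — clustered faces with bipolar voltage < 0.5 mV (dense
     scar), extent as % of occupied faces.
   - **IMP1..IMP8** — regional mean impedance.

3. **Risk modelling.** Variable screening (missingness < 10% non-missing,
   constant columns, < 5% heterogeneity, operator-dependent flags), median/
   mode imputation fitted on training rows only, stratified 80:20 train/test
   split with 3-fold cross-validation inside the training set, model families
   `logistic`, `linear`, `linear-svm`, `rbf-svm`, `ann`, exhaustive subset
   search over a pre-ranked candidate pool ranked by CV AUC, and the six
   metrics AUC(train)/AUC(test)/accuracy/precision/sensitivity/specificity.
   Nonlinear models are attributed with Shapley values (exact coalition
   enumeration up to 10 features, permutation sampling beyond).

4. **Synthetic cohorts.** Because clinical EAM exports are not public, a
   first-class generator produces mapping exports with planted substrate
   abnormalities (scar patches, late patches, unipolar-depression patches, a
   conduction-isthmus activation ramp) plus a clinical covariate table, and
   assigns outcomes from a stated generative logistic model
   (`outcome_model()`, default: logit P(MAE) = −21.007 + 3.889·NYHA +
   0.262·PAP + 0.034·LAT + 0.492·GR + 2.638·Hypertension), so the whole
   pipeline is testable with known ground truth.

## Worked example

```r
library(eamrisk)

sphere <- build_sphere()                     # 14,400 equal-area faces
scenario <- substrate_scenario(
  n_points = 1500, seed = 42,
  scar_patches = list(list(region = 3, radius_deg = 25, mean = 0.25)),
  isthmus = list(region = 5, width_mm = 2, step_ms = 45))
map <- generate_map(scenario, sphere)
map
#> eam_export 'synthetic-000042': 1500 points
#>   bipolar 0.00-4.10 mV, unipolar 5.40-10.32 mV, LAT -38.2-29.4 ms

features <- extract_features(map, sphere)
round(unlist(features[c("GR", "ScarAreas", "VLT", "LAT")]), 2)
#>        GR ScarAreas       VLT       LAT
#>     10.88      1.98      1.27      1.43
round(unlist(features[paste0("GR", 1:8)]), 2)
#>   GR1   GR2   GR3   GR4   GR5   GR6   GR7   GR8
#> 14.27 12.91 19.46 24.66 44.37 10.21 17.60 13.38
round(unlist(features[paste0("Scar", 1:8)]), 2)
#> Scar1 Scar2 Scar3 Scar4 Scar5 Scar6 Scar7 Scar8
#>  0.00  0.00 14.97  0.00  0.00  0.00  0.00  0.00
```

The planted isthmus in region 5 dominates the regional gradients
(GR5 = 44.4 ms/mm vs ≤ 24.7 elsewhere) and the scar patch planted in
region 3 is the only region with non-zero scar extent (Scar3 = 15% of that
region's occupied faces; globally 1.98% of all occupied faces). The scalar
GR (10.9) is the 95th percentile of per-point gradients, dominated by the
ramp; VLT and LAT pick up only noise-level clusters because no
voltage-discrepancy or late-potential patch was planted.

A full synthetic study — cohort generation, feature extraction, screening,
model search and report files — runs from one config:

```r
run_pipeline(run_config(n_patients = 30, seed = 1), "my_run")
```

or from the shell via `Rscript inst/cli/eamrisk.R run --seed 1 --out my_run`
(subcommands: `simulate`, `extract`, `train`, `report`, `run`).

## Notes

- All synthetic data are statistical surrogates: channels are drawn from
  documented distributions with planted effects, not biophysical electrogram
  simulations. See the methods vignette (`vignettes/eamrisk-methods.Rmd`)
  for the model, its assumptions, parameter defaults and limitations.
- Exports are read/written in a plain TSV dialect
  (`x y z alpha beta gamma uni_v bip_v lat imp`, 6-decimal fixed format,
  optional gzip); no proprietary mapping-system archives are parsed.
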