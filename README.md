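# gpatlas

Probability atlas of atrioventricular-dissociating ganglionated plexus
(AVD-GP) sites on the left atrium.

## The problem

The intrinsic cardiac autonomic nervous system clusters into epicardial
ganglionated plexuses (GPs). During atrial fibrillation (AF) ablation
studies, endocardial high-frequency stimulation (HFS; 20 Hz bursts) can
probe each left-atrial site: at a GP site the stimulus slows or blocks AV
conduction — the ventricular response becomes asystole or marked
bradycardia — while elsewhere it has no ventricular effect. Mapping
hundreds of sites per patient and pooling patients onto one reference
anatomy yields a spatial probability map of where AVD-GPs live.

`gpatlas` implements that analysis chain for electrophysiologists and
computational-anatomy researchers, plus a fully synthetic cohort
generator so every stage can be validated against known ground truth:

1. **Response classification** (`hfs_rr_stats()`, `classify_site()`).
   With baseline mean RR interval `RR0` (mean of the 10 RR intervals
   before HFS) and stimulation statistics, a site is

   * `A_AVD_GP` (asystole) if any single RR during HFS `> 2.5 x RR0`
     (equivalently a > 150 % single-RR prolongation),
   * `B_AVD_GP` (bradycardia) if the mean RR during HFS `>= 1.5 x RR0`
     (>= 50 % increase) without asystole,
   * `NEGATIVE` otherwise.

2. **Threshold calibration** (`derive_asystole_threshold()`). From 20 s
   baseline AF segments, the ratio (longest RR in the last 10 s) / (mean
   RR of the first 10 s) is log-normal; the asystole cut-off is the
   one-tailed 1 % quantile `exp(mu_log + 2.33 * sd_log)`.

3. **Surface registration** (`register_surfaces()`). Each patient's
   labelled left-atrial mesh is registered to a reference shell:
   circumferential landmark rings are generated at the four pulmonary
   vein (PV) junctions (detected as the maximal-curvature cutting plane
   along each vein), per-PV ring phases are selected by grid search, and
   a similarity (Procrustes) transform plus thin-plate-spline warp maps
   sites onto the reference. Accuracy is the target registration error
   (TRE): the mean distance of held-out landmarks after mapping
   (0 = perfect).

4. **Probability atlas** (`patient_field()`, `cohort_average()`,
   `find_peaks()`, `area_concentration()`). Each tested site carries
   outcome 1 (AVD-GP) or 0 (negative) and a Gaussian kernel of scale
   sigma = 5 mm (catheter-position uncertainty). The per-patient field
   at x is the kernel-normalised weighted outcome
   `sum(p_i w_i(x)) / sum(w_i(x))`; patients are averaged vertex-wise
   (masked where untested); peaks are edge-connected components above
   20 % probability.

5. **Synthetic cohorts** (`simulate_cohort()`, `run_pipeline()`).
   Parametric 4-PV atrial shells with analytically known junction
   geometry, smooth random patient deformations with exact
   correspondence, ~75 evenly spread HFS sites per patient at a ~6 mm
   coverage target, hotspot-structured ground-truth GP fields, and
   R-wave series realising each site label.

## Worked example

```r
library(gpatlas)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 3, sites_per_patient = 60, seed = 42),
  phase_grid_steps = 8)
res <- run_pipeline(cfg, progress = FALSE)
print(res)
#> <gp_pipeline_result> 3 patients, 165 sites tested
#>   AVD-GP: 21 (12.7%); A 18 (86% of GP), B 3 (14%)
#>   TRE 0.21 +/- 0.04 mm; 7 atlas peaks (74%, 54%, 51%, 49%, 48%, 30%, 24%)
#>   17% of surface area contains 90% of AVD-GPs
```

Reading the output: 165 HFS sites were simulated, classified from their
R-wave series, registered onto the reference shell and pooled; 12.7 %
showed AV dissociation, split 86/14 between asystolic and bradycardic
responses. Registration accuracy (held-out TRE) averaged 0.21 mm on
these smooth synthetic anatomies. With only 3 patients the atlas is
noisy — 7 small components exceed the 20 % threshold — whereas a full
20-patient cohort resolves exactly the three generator hotspots (see the
acceptance suite). The final line is the area-concentration statistic:
the most probable 17 % of the atrial surface already contains 90 % of
the AVD-GP sites.

Threshold calibration on simulated AF variability:

```r
der <- derive_asystole_threshold(simulate_af_ratios(500), tail_mass = 0.01)
print(der)
#> <threshold_derivation> n=500  Shapiro-Wilk p=0.954
#>   log-ratio mean 0.3938, sd 0.2462; z=2.33 (tail 0.01)
#>   derived ratio threshold 2.629 (operational 2.50)
```

A command-line wrapper lives in `inst/cli/gp-atlas`
(`simulate`, `classify`, `calibrate`, `register`, `atlas`, `run`).

## Documentation

The methods vignette (`vignettes/gp-probability-atlas.Rmd`) describes
the model, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical choices, and
known limitations.
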