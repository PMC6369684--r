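---
title: "Mapping AV-dissociating ganglionated plexus sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping AV-dissociating ganglionated plexus sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gpatlas)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic world does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Classifying the ventricular response to HFS

High-frequency stimulation (20 Hz burst pacing) at an endocardial site
overlying a ganglionated plexus excites autonomic fibres that slow or
block AV-nodal conduction. Because the atria fibrillate under HFS, the
*ventricular* RR series is the only usable readout; R-peaks are assumed
extracted upstream (arterial pressure trace or right-ventricular
electrogram) and this package starts from R-wave times in milliseconds.

**Baseline.** The mean of the 10 RR intervals immediately preceding HFS
(`baseline_mean_rr()`). The window is beat-count-based, not time-based:
the later 10-second windows appear only in the AF-variability
calibration, which is where they are used clinically. A series with
fewer than 11 pre-HFS R-waves is rejected, never silently padded.

**Response statistics** (`hfs_rr_stats()`). Let `t_first` be the first
R-wave at/after HFS onset and `t_last` the first R-wave at/after HFS
cessation. The mean HFS RR interval is `(t_last - t_first) / k` with `k`
the number of RR intervals spanned; the maximum HFS RR is the longest
single interval whose right endpoint lies in `(hfs_start, t_last]`. Two
deliberate edge rules:

* the interval *bridging* HFS cessation counts toward the maximum —
  an asystolic pause typically spans the moment the operator stops HFS;
* if no R-wave falls inside the window at all (asystole from the first
  beat), the single bridging interval from the last pre-HFS R to the
  first post-HFS R serves as both mean and maximum. The clinical protocol
  does not specify this case; the bridging rule is the only choice that
  neither discards the most extreme responses nor invents beats, and it
  is pinned by tests.

**Labels** (`classify_site()`). Asystole (`A_AVD_GP`) if
`max_ratio > asystole_ratio_threshold` (default 2.5, *strict*,
following "more than 2.5 times"); else bradycardia (`B_AVD_GP`) if
`mean_ratio >= mean_increase_threshold` (default 1.5, *inclusive*,
following "more than or equal to 50%" — the occasional ">50%" phrasing
is treated as loose restatement); else negative. The asystole criterion
is checked first, so bursts stopped at asystole onset label `A`
regardless of their mean ratio. Classification is monotone in both
ratios (property-tested).

## 2. Calibrating the asystole threshold

Ordinary AF irregularity occasionally produces a long RR without any
autonomic cause, so "how long is abnormally long?" is calibrated from
baseline AF variability. Each 20 s AF segment contributes the ratio of
its longest RR in the last 10 s to its mean RR of the first 10 s;
ratios are treated as log-normal (Shapiro-Wilk on the log-ratios is
computed and reported, not enforced — a small p-value flags the
assumption but does not abort a calibration the analyst may still
want). The threshold is the one-tailed upper quantile

```
exp(mu_log + qnorm(1 - tail_mass) * sd_log),   tail_mass = 0.01,
```

so fewer than 1% of innocent AF pauses are misread as asystole. The
multiplier is *computed* from `qnorm`, not hard-coded: 2.33 is its
2-d.p. display at the 1% tail. The derived value on realistic
variability comes out near 2.6; the operational default stays at the
rounded 2.5 the clinical protocol used (the rounding rationale is not
recorded in the protocol; we treat it as an operational simplification
and keep both numbers visible in `threshold_derivation` objects).
`shapiro.test()` accepts at most 5000 points, so larger calibration sets
are subsampled deterministically (evenly spaced order statistics) for
the normality report only.

## 3. Surface representation and PV junction landmarks

Meshes are plain triangle soups with per-vertex region labels
(`BODY`, four PVs, `MV_RIM`), in millimetres, validated for degenerate
triangles and unreferenced vertices. IO covers ascii PLY, OBJ, legacy
VTK polydata and a documented CSV dialect (`vertices.csv` /
`faces.csv`, 0-based indices); labels ride in a sidecar CSV when the
format has no attributes.

**Junction detection** (`find_junction_plane()`). The PV-atrial
junction is located by sweeping cutting planes orthogonal to the vein
axis and scoring each plane's intersection ring by the surface
curvature along it:

* *Axis*: initial estimate from the body centroid to the PV-region
  centroid, then refined by fitting a line through intersection-ring
  centroids in the tubular (outer) part of the vein, where ring centres
  lie on the true axis. The cutting-plane orientation is not specified
  by the clinical method ("a plane"); orthogonal-to-axis is our choice.
* *Score*: the ring mean of the per-vertex measure `(|k1| + |k2|)/2`
  (mean absolute principal curvature), from the cotangent-Laplacian
  mean curvature and angle-deficit Gaussian curvature, linearly
  interpolated along each crossed mesh edge. The clinical method names
  no curvature measure; this one is robust on discrete meshes and peaks
  at the ostial flare.
* *Selection*: arg-max over the sweep; ties (a uniform tube) resolve to
  the plane closest to the atrial body. One numerical subtlety: the
  continuous measure *steps down* where the concave fillet meets the
  tube, and discrete curvature blurs that step over about one vertex
  ring, biasing the raw arg-max into the fillet. When a clear step is
  present (>= 25% score drop within a few planes outward) the plane is
  relocated to the quadratically interpolated steepest-descent point —
  standard sub-resolution edge localisation, unbiased for a
  symmetrically blurred step. Localisation is still resolution-limited
  to roughly half a vertex ring (~1 mm at the default mesh density;
  tests that compare against the generator's closed-form junction
  geometry use one extra subdivision level).
* Rings are found by intersecting the *whole* mesh with each plane and
  keeping the closed curve nearest the axis; restricting to labelled
  faces breaks rings on tilted or deformed anatomies.

**Landmarks** (`generate_landmark_ring()`). `n` points (default 8; the
count is not stated clinically and is exposed as configuration) at
equal polar angles `phase + k*2*pi/n` about the ring centroid. Angle
zero is the projection of a reference axis — by default the global
superior (+z) axis — onto the ring plane, so phases are comparable
across co-registered patients. A fixed global axis cannot itself be
equivariant under rigid motion; the equivariance property holds (and is
tested) when the reference axis is co-rotated with the mesh. Landmark
angles are exact: the angle condition is linear along each curve
segment and solved in closed form rather than by chord interpolation.

## 4. Registration and target registration error

Per patient: similarity (Procrustes/Umeyama rotation + isotropic scale
+ translation, closed form) on the *used* landmark pairs, then a 3D
polyharmonic thin-plate spline (kernel `U(r) = r`) on the
similarity-aligned used landmarks. With regularisation `lambda = 0`
(default) the warp interpolates its landmarks exactly and reproduces
affine maps exactly — both properties are test-pinned; `lambda > 0` is
exposed for noisy landmarks. Mapped points are finally projected to the
closest point on the reference surface. The nonrigid family is our
choice ("nonrigid surface registration" is otherwise unspecified):
landmark-driven, deterministic, and with testable exactness properties.

**TRE** is the mean distance between mapped *held-out* landmarks and
their true reference positions; held-out pairs are the odd-indexed ring
points (used = even) — the clinical description says held-out landmarks
were excluded from fitting but not how they were chosen. **Phase
selection** grid-searches each PV's ring phase over `[0, 2*pi/n)`
(default 16 steps), sweeping coordinate-wise twice and then refining
jointly over the one-step neighbourhood, minimising held-out TRE; ties
break to the lexicographically smallest phase vector. All of
registration is deterministic.

Whether the clinical TRE of "2.7 +/- 1.0 mm" was averaged per landmark
or per patient is not stated; we compute per-patient TREs and report
their cohort mean +/- SD. On the synthetic cohort the suite asserts
comparability (mean TRE <= 3 mm), not equality: the generator's smooth
low-order deformations are much kinder than real anatomical variation,
and measured synthetic TREs are well under a millimetre.

## 5. The probability atlas

Sites carry outcome 1 (AVD-GP, either subtype) or 0 (negative). At a
vertex `x`, site `i` contributes weight
`w_i = exp(-d(x, x_i)^2 / (2 sigma^2))`; the per-patient field is
`sum(p_i w_i) / sum(w_i)` — a Nadaraya-Watson estimate of the local
AVD-GP probability.

* **Kernel scale.** "A Gaussian kernel with a variance of 5 mm" is read
  as *scale* sigma = 5 mm (variance 25 mm^2): the companion text calls
  the same footprint a "5-mm-radius" uncertainty and draws 5 mm circles.
  The alternative (sigma^2 = 5 mm^2) is selectable via `sigma_mm`.
* **Metric.** 3D Euclidean, not geodesic: no metric is specified
  clinically, the kernel is small relative to wall curvature, and
  Euclidean matches the printed circular footprints. On folded regions
  (PV ostia) Euclidean proximity can couple surface patches that are
  geodesically distant; geodesic distance is a noted extension.
* **Masking.** Values are UNDEFINED where the total kernel weight falls
  below the kernel value at 3 sigma (one site farther than ~3 sigma
  from everything defines nothing) — the clinical maps show untested
  areas as blank without defining them, so the cutoff is ours.
* **Cohort averaging** is the vertex-wise *masked* mean over patients
  with defined values, never imputing 0: "not tested" is not "tested
  negative". Per-vertex contributor counts are recorded.
* **Peaks** are edge-connected components of vertices *strictly* above
  the 20% threshold ("greater than 20%"), each summarised by its
  maximum-probability vertex, sorted by peak probability. Anatomical
  naming is left to the analyst (free-text annotation).
* **Area concentration** ranks triangles by mean vertex probability
  (undefined last, ties by index) and accumulates area until the region
  holds the requested share (default 90%) of AVD-GP sites, each site
  assigned to its nearest triangle. The clinical "48% of the area held
  90% of GPs" statistic names no algorithm; this probability-ranked
  greedy accumulation is an explicit reconstruction.

## 6. The synthetic world

The generator emulates the three input classes end to end, with one
master seed reproducing everything.

**Geometry.** The reference shell is a mildly ellipsoidal body
(semi-axes 27/25/23 mm — left-atrial scale) with four PV stubs
(radius 6 mm, length 8 mm) joined by 4 mm fillets, built on a
subdivided icosphere (default level 5, ~9300 vertices after opening the
mitral orifice and vein ends). Around each vein the surface is an
*exact* surface of revolution (sphere cap, toroidal fillet, cylinder):
the PV profile is added to the ellipsoid radius as a delta that
vanishes smoothly at the sphere tangency, so junction curvature is
known in closed form and junction detection can be tested against an
analytic oracle. An angular remap concentrates mesh resolution in the
tube/fillet band. PV axes are placed so vein cones, the mitral cone and
hotspots do not collide; coordinates follow the electroanatomic
convention (+z superior, +y posterior, mm).

**Patients.** A random degree-1/2 spherical-harmonic radial field
scaled to RMS `deformation_scale_mm` (default 3 mm), then a random
rigid motion (rotation up to ~15 degrees, translation +/- 10 mm).
Patient meshes share the reference topology, so the exact forward
correspondence (face + barycentric identity) is available to oracles.
Deformations large enough to risk folding are damped with a message.

**Sites.** Greedy farthest-point selection from a dense uniform-by-area
candidate pool — a Poisson-disk-like layout targeting the clinical
"even mapping within 6 mm" protocol. The 6 mm figure is read as a
*coverage* target (dense, even mapping), not a hard minimum pairwise
distance: the protocol sentence is ambiguous and even coverage is its
evident intent. Counts are drawn around 75 per patient (clamped to
+/- 20%); infeasible packings error out with the achievable bound.

**Ground truth and labels.** The true AVD-GP probability field is a
background plus three Gaussian hotspots (scale 5 mm) whose geography
echoes the clinically reported concentration regions: one centre near
the RSPV antrum, one at the RIPV base on the posterior wall, and one
septal centre placed anteriorly. Centres snap to the best-aligned
atrial-body vertex so an "antral" hotspot cannot land on the protruding
vein stub. Amplitudes 0.70/0.55/0.50 over background 0.05 were fixed a
priori so that, after kernel attenuation (factor s^2/(s^2+sigma^2) =
0.5 for bump scale s = 5 and sigma = 5), atlas peaks echo the reported
~41/31/30% and stay separable at the 20% threshold: on this 25 mm-scale
chamber the clinical peak regions sit closer together than kernel
separability allows, so inter-hotspot spacing (>= ~25 mm) was
prioritised over literal geography — and the overall AVD-GP rate
(~8-10% here) was *not* raised to the clinical 13%, because a higher
background would push inter-peak saddles over the 20% threshold and
merge the peaks. Pipelines that need the 13% rate set
`field_mean_target = 0.13`, which raises the background only. Site
labels are Bernoulli draws from the field (optionally scaled by a
per-patient log-normal amplitude factor, default log-SD 0.3, emulating
the strong clinical between-patient spread in GP counts — its true
source is unknown); AVD-GP sites split A/B at 0.8, the clinical 80/20.

**R-wave series.** Baseline AF RR intervals are log-normal (median
~700 ms, log-SD 0.15). Negative sites continue baseline variability
through the 10 s window; bradycardia sites scale in-window intervals to
a mean ratio drawn from [1.6, 2.2] with single intervals capped at
2.25x baseline; asystole sites insert a pause of 3-5x baseline with
HFS stopped mid-pause. Calibration-grade variability ratios are drawn
from a log-normal whose 99th percentile sits at ratio 2.6 (log-mean
0.405, log-SD 0.2367). No waveforms are synthesised — the R-peak series
is the unit of simulation.

**What a green test does not establish.** The generator's anatomies
deform smoothly and share topology with the reference; real atria vary
topologically (common ostia, accessory veins — explicitly out of
scope), segmentations carry noise, and catheter localisation errors are
not simulated beyond the kernel's own uncertainty model. Synthetic TREs
near zero therefore validate the *machinery*, not clinical accuracy;
the clinical 2.7 +/- 1.0 mm anchors the order of magnitude only.
Likewise the atlas-recovery tests validate estimator correctness under
the stated noise model, not the clinical map. One acceptance
expectation — atlas-truth correlation > 0.8 on the fixed-seed
20-patient cohort — is knife-edge by design arithmetic: even a
zero-error pipeline's correlation distribution straddles 0.8 at this
cohort size (the kernel-smoothed truth itself correlates 0.93 with the
raw field; Bernoulli site noise does the rest), and we left the fixed
seed and generator world untouched rather than nudge either toward the
threshold, so that expectation can fail honestly while its companions
(3/3 hotspots recovered within 10 mm; TRE <= 3 mm) hold.

## 7. Numerical choices and degenerate inputs

* Landmark angles and Procrustes/TPS solves are closed-form; no
  iterative optimisation anywhere except the phase grid search, which
  is exhaustive and deterministic. No random initialisation exists in
  the registration path.
* Collinear landmark sets, coincident TPS control points, empty
  held-out sets, non-tubular PV label patches, infeasible site
  packings, truncated recordings and too-few-baseline-beats all raise
  informative errors rather than degrade silently.
* Plane-mesh intersection nudges exact vertex hits by 1e-12 mm to keep
  the crossing combinatorics stable; landmark placement then re-solves
  exactly on the resulting segments.
* The uniform-curvature sweep tie-break (closest plane to the atrial
  body) is deterministic and test-pinned; the sub-resolution step
  refinement only engages when a >= 25% score drop marks a real ostium.
* Binary PLY is detected and rejected with a clear message (ascii PLY,
  OBJ, VTK, CSV are supported); meshes round-trip losslessly through
  the CSV dialect and to ascii float precision elsewhere.

## 8. Known limitations

* Euclidean kernels on folded anatomy (see section 5); geodesic
  distance is the natural extension hook.
* Junction localisation is mesh-resolution-limited (~half a vertex
  ring); very coarse clinical exports would need remeshing.
* The area-concentration statistic and the held-out-landmark split are
  explicit reconstructions of under-specified clinical procedures;
  alternative conventions would shift those numbers.
* The left-atrial appendage is treated as body wall; right-atrial GPs
  and ablation effects are out of scope.
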