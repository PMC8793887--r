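---
title: "VoxelFlow: models, parameters and design choices"
author: "VoxelFlow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VoxelFlow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VoxelFlow)
```

## What the package computes

4D-flow MRI measures a three-directional velocity vector $v(t)$ in every
voxel of a 3-D volume across the cardiac cycle, together with a signal
magnitude image. Given such a series and a binary segmentation of the
thoracic aorta, VoxelFlow derives voxel-by-voxel hemodynamic parameters and
summarises them over the five standard aortic regions — left ventricular
outflow tract (LVOT), ascending aorta (AAo), arch, proximal and distal
descending aorta (PDAo, DDAo):

* **Forward / reverse flow (FF / RF, mL/cycle).** Every lumen voxel is
  matched to the nearest centreline point (shortest 3-D distance, upstream
  index on ties); the point's tangent defines downstream. Per frame, the
  tangent-projected velocity $v_\parallel$ times the 1 mm² voxel face times
  the frame duration is a moved volume; positive projections accumulate
  into FF, negative into RF, summed over the cycle. With this convention a
  steady 0.15 m/s axial flow gives 0.15 mL/cycle per voxel, the magnitude
  scale typical of voxel-wise aortic mapping.
* **Stasis (%).** The percentage of cardiac frames in which the voxel speed
  $|v(t)|$ stays below 0.1 m/s. Speed, not axial velocity, is used: slow
  flow is slow regardless of direction.
* **Kinetic energy (µJ).** $\mathrm{KE} = \sum_t \tfrac12\,\rho\,dV\,|v(t)|^2$
  with blood density $\rho = 1060\ \mathrm{kg/m^3}$ and the unit analysis
  voxel $dV = 1\ \mathrm{mm^3}$, summed (not averaged) over the cycle.
* **Peak velocity (m/s).** The maximum speed over the systolic frames; the
  regional value is the regional maximum (a peak), while FF, RF, stasis and
  KE aggregate as voxel means.
* **Geometry.** Per-region maximum effective diameters
  ($2\sqrt{A/\pi}$ from the cross-sectional area), BSA-indexed diameters
  (Mosteller $\sqrt{hw/3600}$ by default, Du Bois available), dilation
  grading of the AAo maximum (non-dilated < 35 mm ≤ moderate < 45 mm ≤
  severe; the boundary values go to the higher class because the
  conventional strict inequalities leave them undefined), and the Reynolds
  number $\rho v_{peak} D/\mu$ at the vena contracta — the station whose
  cross-section holds the global systolic peak-velocity voxel — with
  whole-blood viscosity $\mu = 3.5\ \mathrm{mPa\,s}$ by default.

A cohort stage mirrors the usual clinical-study analysis: Shapiro-Wilk
(α = 0.05, per group) gates Student's t-test versus Mann-Whitney for two
groups and one-way ANOVA with Tukey contrasts for more; percent change is
$100(\bar x_g - \bar x_{ref})/\bar x_{ref}$, displayed as whole percent;
correlations are Pearson or (if either variable fails the gate) Spearman,
and flagged significant only under the joint rule $p \le 0.05$ **and**
$|R| > 0.25$; the multivariable model regresses the z-scored dependent
variable on z-scored predictors that pass the univariate rule and a
pairwise collinearity screen ($|r| > 0.7$ drops the weaker candidate, a
threshold chosen where variance-inflation concerns conventionally begin),
with age always retained.

## Preprocessing

* **PC-MRA.** $\sqrt{\frac1T \sum_t (M(t)\,|v(t)|)^2}$ — the
  magnitude-weighted RMS speed. Several variants circulate; this one is
  monotone in both magnitude and speed and is frame-order invariant.
* **Noise masking.** Voxels whose time-averaged magnitude falls below a
  configurable quantile (default 0.3) are excluded.
* **Velocity anti-aliasing.** Temporal unwrapping per voxel and component:
  frame-to-frame jumps larger than venc are removed by the appropriate
  multiple of $2\,\mathrm{venc}$. This recovers single-wrap data exactly
  when true speeds stay below $3\,\mathrm{venc}$; voxels still beyond that
  bound afterwards are QC-counted rather than silently accepted. No spatial
  region-growing is attempted.
* **Eddy-current correction.** A first-order (planar) polynomial in space
  is fitted per component to the temporal-mean velocity over static tissue
  and subtracted everywhere. Static tissue is supplied or auto-detected as
  above-noise-floor voxels whose temporal speed variation sits in the
  lowest 20%. The fit removes exactly the artifact the phantom generator
  injects, which gives a machine-precision round-trip oracle.
* **Maxwell terms.** Concomitant-gradient correction needs the sequence
  gradient waveforms, which no offline pipeline has; the slot is an
  explicit, logged pass-through so the preprocessing chain remains honest
  about what it does.

## Isotropic resampling

Acquisition grids (2–3.5 mm, possibly anisotropic) are resampled to 1 mm
isotropic voxels with separable cubic splines before mapping, implemented
as fixed per-axis linear operators (interpolation of the unit vectors);
`fmm` end conditions make the interpolant exact on cubic polynomials, so
constant and linear fields survive unchanged — both are asserted in the
tests. The mask is resampled nearest-neighbour: thresholding a trilinearly
smoothed indicator at 0.5 systematically dilates diagonal surfaces at
coarse spacing, while nearest-neighbour preserves lumen volume essentially
exactly.

## Centreline extraction

No installed package provides a 3-D curve skeleton, so the centreline is
built in-package from standard pieces: an erosion-depth field
(6-neighbour peeling) approximates distance-to-wall; a 26-neighbour voxel
graph with edge weight $\ell/(0.25 + \bar d)^2$ makes core voxels cheap; a
double Dijkstra sweep finds the two mutually farthest lumen ends and the
connecting geodesic. The raw path enters the lumen at a cap-rim voxel, so
the shallow entry ramp is trimmed, the path is moving-average smoothed with
a window comparable to the radius, and each station is then moved to the
centroid of its 1 mm cross-sectional slab. Because an arc-length slab
under-samples the inner side of a bend (the physical arc shrinks by
$1 - u\kappa$ at offset $u$ toward the curvature centre), centroids are
weighted by the inverse metric factor; without this the recovered line
drifts outward by about $\kappa R^2/4$, which is visible at aortic
curvatures. Finally the ends are rebuilt by extending the clean interior
along robust multi-point end tangents to the mask caps (stopping at cap
voxel centres), with the extended stations re-centred in-plane only —
their cap-truncated slabs would otherwise bias a full 3-D centroid. The
result is resampled at 1 mm with ±3-station central-difference tangents.

A centreline from a mask alone has arbitrary orientation;
`orientByFlow()` flips it, together with the voxel assignment, whenever
the cycle-summed projected flow is negative, so "downstream" follows the
net flow. Masks with several components, loops, or too little thickness to
carry a centreline are rejected with named errors: the coverage guard
checks that every mask voxel lies within a radius-scaled envelope of the
single end-to-end path.

Region boundaries are arc lengths supplied per subject (real anatomy needs
landmarks); the phantom default 10 / 45 / 60 / 80 % of the span populates
all five regions.

## The synthetic phantom

The generator emulates what the analysis needs, not MRI physics: pulsatile
laminar tube flow with exact ground truth. Inside a straight or candy-cane
(vertical limb – semicircular arch – vertical limb) lumen of radius $R$,
the velocity is a Poiseuille profile along the local tangent,
$v(r,t) = 2\bar V(t)\,(1 - (r/R)^2)$, optionally plus an azimuthal swirl
component scaled by $r/R$ and the waveform envelope, Gaussian noise, venc
wrapping and spatially linear offsets. Truth objects carry the analytic
centreline, per-station flow rate $\bar V(t)\pi R^2$, per-voxel stasis and
cycle-summed KE, and the mask.

Defaults are acquisition-like and deliberately coarse so the 1 mm
re-interpolation is exercised: 2.4 mm isotropic spacing, 20 frames over a
1000 ms cycle, venc 1.5 m/s, lumen radius 8 mm, limbs 50 mm, arch radius
42 mm. The default waveform is a half-sine systole over the first 35 % of
the cycle with peak mean velocity 0.8 m/s, a small early-diastolic
retrograde lobe (10 % of peak over the next 15 %) and zero diastole —
plausible for an aorta, not a reproduction of any measured curve. The
spec-level `retrogradeFraction` is a sign-mixing knob,
$\bar V_{eff} = (1 - 2f)\bar V$: 0 leaves the waveform alone, 1 reverses
the flow at every station exactly, and intermediate values attenuate net
forward flow; sustained retrograde content is instead controlled through
the waveform's lobe. Seeds are explicit everywhere and the generator is
bit-reproducible.

What the phantom does **not** model — Womersley profiles, turbulence,
partial-volume and k-space effects, wall motion — bounds what green tests
mean: they certify the numerics of the mapping chain (conservation,
geometry recovery, oracle equality, calibrated statistics), not robustness
to everything clinical data can contain.

The cohort simulator draws subject-level regional parameters from
published group means and spreads (stored as a plain-text table in
`inst/extdata/`): log-normal with moment matching for strictly positive
parameters (FF, RF, KE, peak velocity, diameters) to avoid negative draws,
normal clipped to [0, 100] for stasis, normal for age (truncated at 18)
and BSA, with valve-type and surgery frequencies matching the published
cohort composition.

## Numerical choices and degenerate inputs

* Grids are indexed with world coordinates `origin + (index − 1) · spacing`
  (mm); the 1 mm output grid is snapped to whole-spacing world coordinates.
* Nearest-point ties break toward the lower (upstream) centreline index —
  deterministic and upstream-biased.
* Station cross-sections are slabs of thickness
  `max(arc step, voxel spacing)`; per-station areas get a 3-station moving
  average to suppress discrete matching jitter without masking real
  calibre change (a 12 mm fusiform bulge is recovered at full amplitude in
  the tests).
* Systole is the contiguous window around the frame of maximal spatial-mean
  lumen speed, extended while that mean stays ≥ 25 % of its peak
  (configurable); an all-zero field yields all frames with a warning.
* Empty regions and empty cross-sections are reported as missing (NA) with
  QC counts, never as zero. Comparisons with under-3-subject groups skip
  the normality gate and go non-parametric with a warning.
* End-to-end runs are deterministic under a fixed seed; the provenance
  JSON records constants, boundaries, seed and QC counters.

Problem sizes used in the test-suite and acceptance checks — a candy cane
of ≈ 47 × 13 × 47 acquisition voxels (≈ 40 000 lumen mm³) at 20 frames,
1000-replicate null calibrations, 100–200-replicate power runs — were
chosen as the smallest sizes at which the discretisation effects under
test are still clearly visible.

## Known limitations

* FF/RF conservation degrades to ≈ 5 % at the limb–arch junctions where
  the tangent field turns fastest; mid-limb and apex cross-sections
  conserve to ≈ 3 % at 2.4 mm acquisition spacing.
* The temporal-only unwrapping cannot fix wraps present in the first frame
  or multi-wrap jumps; such voxels are only counted.
* The centreline needs a tube at least ~2 voxels of erosion depth thick;
  thin or plate-like masks are rejected rather than guessed at.
* Printed bracketed percent changes in the source cohort tables do not all
  recompute from the printed (rounded) group means; the worked examples
  shipped here are the subset that does.
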