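---
title: "Adaptive thresholding of moving lung tumors on PET: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive thresholding of moving lung tumors on PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmsbr)
```

## The problem

A lung tumor that moves with respiration is imaged by PET as a blurred
object smeared over its motion envelope — the union of positions it
occupies during the breathing cycle.  For radiotherapy planning that
envelope *is* the internal target volume (ITV), so a threshold placed
correctly on the blurred activity map can delineate the ITV directly.
The difficulty is that the correct threshold varies lesion by lesion:
small tumors lose apparent contrast to partial-volume averaging, moving
tumors dilute their activity over a larger envelope, and the achievable
contrast is bounded by the tumor-to-lung background ratio.

## The model

The VMSBR model summarizes phantom calibration measurements as a linear
model for the log of the optimal threshold `w`, normalized to background
activity:

$$\ln w = c_0 x^{1/3} + c_1 y^{1/3} + c_2 \ln z + c_3 x^{1/3}\ln z +
  c_4 y^{1/3}\ln z + c_5 (xy)^{1/3} + c_6$$

with tumor volume $x$ (cm³), peak-to-peak motion $y$ (mm) and
source-to-background ratio $z$.  Cube roots make the size and motion
terms scale like lengths; the interactions let contrast modulate how
strongly size and motion shift the threshold.  The default coefficients
are `r paste(sprintf('%.4f', as.numeric(vmsbr_coefficients())), collapse = ', ')`.

The SBR measured on a blurred image underestimates the true contrast, so
it is corrected before entering the model:

$$\mathrm{RC} = r_0 x^{-1} + r_1 y + r_2 x^{-1} y + r_3, \qquad
  z = \mathrm{SBR}_\text{measured} \times \mathrm{RC}$$

with defaults `r paste(sprintf('%.4f', as.numeric(rc_coefficients())), collapse = ', ')`.
RC decreases with volume and increases with motion: small, fast lesions
need the most correction.  Both coefficient sets can be refit from
simulated calibration data with `vmsbr_fit()` / `rc_fit()` (plain OLS on
the fixed bases, in log space for the threshold model so multiplicative
threshold errors become additive; no regularization — 7 parameters
against hundreds of records).

### Measurement conventions

* **SBR on an image** (`measure_sbr()`): tumor mean AC by a two-step
  plateau rule — the mean of voxels above 70 % of ACmax, then the mean of
  voxels at or above 80 % of that plateau mean.  The published
  description ("a ROI at 80 % of ACmean") is circular as written; the
  one-step interpretation is deterministic and is the package's declared
  reading.  Background is the mean over the lung compartment after
  removing exclusion masks and, by default, voxels above
  median + 3 MAD (automating the removal of hot spots from the
  background sample).
* **Absolute threshold**: `w × background AC`.  The model's `w` is
  normalized to background; where a percent-of-ACmax scale is needed
  (threshold scans), the bridge is
  `w_opt = fraction_opt × ACmax / background AC`.
* **Volume and motion inputs** come from CT in clinical use; in the
  simulator they are the known sphere volume and motion, and in fixture
  mode the packaged cohort values.

## The simulator

`simulate_pet()` models the post-reconstruction image, not tomography:
ideal sphere occupancy (supersampled 3× for partial-volume boundary
voxels) → arcsine motion blur along one axis → isotropic Gaussian PSF →
optional additive Gaussian noise.  The arcsine kernel is the dwell-time
density of sinusoidal motion, integrated over voxel-width bins so it
sums to one exactly; a constant background is invariant under the
normalized blurs, so total activity is conserved whenever the default
padding (3 × FWHM) is respected.

Key defaults, chosen once as representative study conditions:

| parameter | default | rationale |
|---|---|---|
| PSF FWHM | 6.5 mm | typical effective resolution of whole-body PET after iterative reconstruction |
| PET grid | (3.91, 3.91, 3.27) mm | 50 cm field of view on a 128×128 matrix, 3.27 mm slices |
| CT-like grid | (0.98, 0.98, 2.5) mm | 512 matrix, 2.5 mm slices |
| background | 3000 Bq/mL | typical lung background activity |
| noise | off | the optimal-threshold geometry is a noiseless-limit concept; noise exists for robustness studies |
| motion envelope | union over 64 phase samples | envelope discretization error below voxel size for extents ≤ 30 mm |
| calibration design | 6 diameters × 7 motions × 6 SBRs = 252 | six NEMA-IEC sphere diameters (10–37 mm), motions 0–30 mm, SBR 2–50; the factorial decomposition of the published 252-point design is not stated, so 6×7×6 is this package's declared choice |

"Motion extent" always means peak-to-peak displacement; the sinusoid
amplitude is half of it.  The matched CT-like MIP (`simulate_ct_mip()`)
assigns 0 HU to the envelope and −800 HU to lung, blurred at 1 mm, so
that −425 HU region growing reproduces the reference-ITV workflow.

What the simulator does *not* emulate: tomographic reconstruction
artifacts (Gibbs overshoot, noise correlation), attenuation and scatter,
respiratory irregularity, aspherical or heterogeneous lesions.  Passing
tests on this simulator therefore validate the *pipeline* — measurement
rules, threshold computation, region growing, surface metrics — and the
functional form's fit behaviour, not scanner-specific accuracy.

## Surface metrics

Masks are meshed by marching tetrahedra on the 0.5 level of the binary
field, after a one-voxel-sigma Gaussian anti-aliasing step (skipped
automatically for masks too small to survive it).  The smoothed level
set tracks the underlying smooth boundary far better than the blocky
midpoint surface: a 15 mm-radius sphere meshes to within 1 % of its
analytic area, where the raw 0/1 surface would bias areas upward by tens
of percent.  Meshes are watertight by construction (shared interpolated
edge vertices); zero-area faces are dropped.

`surface_separation()` averages exact point-to-triangle distances from
sampling points on the reference mesh (all vertices, plus face centroids
for meshes under 500 vertices) to the other surface.  It is one-sided by
default with the reference (CT-derived) surface as the yardstick — the
convention of the optimality criterion — with a symmetric option.
`optimal_threshold_scan()` segments at 1 %–99 % of ACmax in 1 % steps,
meshes each result, and returns the fraction minimizing the mean
separation; ties break toward the lower (more inclusive) fraction, and
fractions where the seed falls below threshold are recorded as absent.

## Numerical and design choices

* Region growing uses inclusive predicates (≥ / ≤) and 6-connectivity by
  default (26 available) — deterministic ties, conservative adjacency.
  The planning-system grower's connectivity is not published; 6 is this
  package's default.
* Voxel indices are 1-based (R convention) with a voxel-center world
  mapping; masks share their image's geometry by construction, so
  volumes in cm³ are consistent everywhere.
* Activity is carried in Bq/mL throughout; SUV is computed on demand
  from the scan calibration.  The iterated SUVmean method interprets its
  linear function as producing a threshold in SUV units, converted to
  Bq/mL through the calibration.
* The mean-plus-background method takes its background from an explicit
  ROI (a 2 cm cube placed deterministically in the background
  compartment in synthetic scenes), since "the adjacent structure with
  the highest background activity" is observer-dependent.
* Not-segmentable handling: every method returns either a finite
  positive threshold or an explicit flag when the threshold does not
  exceed the measured background — never a silently empty mask.  Flagged
  lesions are excluded pairwise from cohort statistics and the remaining
  pair count is reported.
* Percent volume differences use the mean reference volume over the same
  paired subset as denominator.  Paired comparisons use two-sided paired
  t-tests at 0.05 with no multiple-testing correction.
* Calibration records whose optimal fraction hits the scan boundary are
  flagged and dropped by default before fitting.

## Problem sizes

The validation pipeline runs six noiseless lesions spanning volumes
1–28 cm³, motions 0–15 mm and SBRs 5–30 at 2 mm isotropic simulation
voxels; calibration experiments in the test suite use 27–36 phantom
configurations at 2–2.5 mm voxels.  These sizes keep surface
discretization error well below the 2 mm agreement scale of interest
while remaining desk-scale.

## Known limitations

* The published coefficient sets encode the optimal-threshold geometry
  of the scanner and reconstruction they were calibrated on.  In this
  package's Gaussian-blur simulator the scan-measured optimal thresholds
  correlate strongly with the model's predictions (rank correlation
  ≈ 0.97 on a 27-point grid) but sit systematically higher, so applying
  the published coefficients to simulated cohorts over-covers the
  envelope in volume terms even while surface agreement stays under
  2 mm.  Users studying volume statistics on simulated data should refit
  the coefficients on the same imaging chain (`calibration_records()` →
  `vmsbr_fit()` / `rc_fit()`), mirroring how the model was developed.
* The recovery model's negative correction (RC < 1) for large stationary
  tumors implies measured SBR can exceed truth on real reconstructions
  (e.g. edge overshoot); a linear blur simulator can only degrade SBR,
  so that regime of Eq-form RC is exercised but not reproduced here.
* Extrapolation below the calibration range (tumors under ~0.5 cm³, the
  smallest phantom sphere) is untested model territory, though the
  functional form remains finite and monotone there.
* One-dimensional sinusoidal motion and homogeneous spherical uptake are
  idealizations; hysteresis, drift, spiculation and necrosis are out of
  scope.
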