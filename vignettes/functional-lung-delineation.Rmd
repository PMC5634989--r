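---
title: "Threshold-based delineation of functional lung volumes: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based delineation of functional lung volumes: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqfv)
```

## The problem

Ventilation/perfusion (V/Q) PET/CT with ⁶⁸Ga-labelled carbon nanoparticles
("Galligas") and ⁶⁸Ga-macroaggregated albumin images regional lung function
directly: where tracer accumulates, lung is ventilated or perfused. The
*functional volume* — the part of the anatomical lung that is ventilated
(or perfused), expressed as a percentage of the whole-lung (WL) volume — is
a quantitative summary of regional function with applications in
radiotherapy planning and pre-surgical evaluation. Manual contouring of
functional lung is accurate but slow and operator-dependent, so a common
automation is a *percentage-of-maximum threshold*: a voxel is functional
when its activity is at least some fraction of the maximal in-lung pixel
value.

This package implements that method end to end — CT lung segmentation,
reference-maximum estimation with airway hot-spot exclusion, threshold
sweeps, the visually-adapted (adaptive) protocol — together with the
agreement statistics used to evaluate it (volume difference, Dice
similarity, Pearson correlation, Bland-Altman limits of agreement) and a
digital thoracic phantom generator that supplies paired CT + V/Q PET
volumes with *known* ground truth, so every stage can be validated
quantitatively.

## The delineation model

**Whole lung.** Aerated lung is radiolucent: `segment_lungs()` thresholds
the CT at −400 HU (midway between aerated lung, ≈ −950 to −500 HU, and
soft tissue, ≈ 0–100 HU), removes air connected to the grid border
(outside the body), keeps the up-to-two largest connected components of at
least 100 ml (left/right lungs, possibly merged at the mediastinum),
applies morphological closing (6 mm ball) and 3-D hole filling (vessels,
nodules), and optionally removes the trachea and main bronchi with a
stricter −950 HU region grow seeded in the top slice. Closing and hole
filling are extensive, so cleanup can only add voxels to the raw threshold
mask. The "visually adjusted" step of clinical practice is exposed as
`manual_adjust()`, a scripted list of spherical add/remove edits, so the
adjustment is reproducible and testable rather than a GUI action.

**Reference maximum.** The functional threshold is a fraction of the
maximal in-lung activity, which makes the method vulnerable to focal
airway deposition of inhaled tracer ("hot spots") in ventilation images: a
single bright focus inflates the maximum, raises every absolute threshold,
and silently shrinks the functional volume. `estimate_max()` therefore
supports the operator policies (`manual_value`, `manual_roi`) and an
automatic one: compute the 99.5th percentile of in-lung activity, flag
26-connected clusters above 1.5 × that percentile with volume ≤ 2 ml
(physiological maxima are broad; deposition foci are small), dilate the
flagged clusters by 8 mm, and take the maximum over the remaining lung.
The dilation matters: after point-spread blur a hot spot has a smooth
penumbra, and excluding only the supra-threshold core would leave the
estimate pinned just below the detection threshold, typically 30–50 % too
high. An 8 mm margin (of the order of the PET point-spread function)
covers the penumbra; on paired phantoms the recovered maximum is within
~1 % of the hot-spot-free maximum. With no flagged cluster the estimate
equals the raw in-lung maximum exactly.

**Threshold sweep.** `delineate_at()` keeps the in-lung voxels with
activity ≥ (cutoff/100) × reference maximum; a voxel exactly at the
threshold is *inside* (a stated tie-break; the convention is otherwise
arbitrary). `threshold_sweep()` evaluates the standard cutoff ladder
5, 10, 15, 20, 25, 30, 40, 50 %max. Because all masks are superlevel sets
of one activity map, they are exactly nested and their volumes
non-increasing, and rescaling the PET by any positive factor changes
nothing — properties the test suite asserts voxelwise rather than
approximately. Functional masks are intersected with the WL mask so that
%WL is well defined and extra-pulmonary activity (airway, stomach) cannot
leak in.

**Adaptive protocol.** A single fixed cutoff transfers poorly between
patients, so the recommended protocol starts at 15 %max and tries
neighbouring thresholds while an explicit objective improves
(`adaptive_delineate()`, greedy walk over a 5–30 %max candidate list).
Two objectives are provided: `match_reference` (minimise |volume
difference| against a reference contour — the evaluation setting) and
`plateau` (minimise the local |dV/dcutoff| — a reference-free surrogate
for an operator judging a contour stable; it is our surrogate, not a
published criterion). The full trajectory is returned for audit. By
construction the walk never returns a worse objective than the 15 %max
start.

## Agreement statistics

`dice()` is 2|A∩B|/(|A|+|B|); two empty masks score 1 (identity), with a
logged warning. `volume_difference()` is signed (auto − reference) in %WL
points. `bland_altman()` uses the standard conventions — sample SD (n−1)
and 1.96 multipliers — so the limits of agreement satisfy
`loa_high − loa_low = 2 × 1.96 × sd` exactly. `pearson()` delegates to
`stats::cor.test` (two-sided t test, n−2 df) and flags p < 0.05; the test
suite checks it against a direct evaluation of the covariance formula.
`summarize_cohort()` aggregates per-case evaluations into the structures a
clinical study reports: per-cutoff mean/SD/min/max volume difference,
median and IQR of Dice, the overall optimal cutoff (argmin |mean
difference|), the per-case optimal-cutoff histogram, and PFT correlations
for both the automatic volume at a report cutoff and the reference.
Volumes are computed at full precision and rounded to one decimal only in
the written report tables. No multiple-testing correction is applied
across the PFT correlation cells, matching standard practice for these
descriptive tables; the choice is logged.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a deliberately simple thorax — two ellipsoidal
lungs (38 × 55 × 75 mm half-axes, ~650 ml each) in an elliptic-cylinder
body — because the quantity under test is the threshold method, not
anatomy. The PET chain reproduces the degradations that matter to a
%max method:

* **anterior–posterior gradient**: activity rises linearly from anterior
  to posterior lung by a fraction `ap_gradient` (default 0.3), emulating
  the gravity dependence of supine V/Q distribution;
* **functional defects**: spheres in which activity is multiplied by a
  factor in [0, 1) (default 0.1), emulating regions of absent function;
* **airway hot spots** (ventilation only): truncated Gaussian blobs with
  peak `intensity_multiplier` × local activity;
* **resolution**: separable Gaussian blur, FWHM 8 mm (clinical PET
  resolution order);
* **counting noise**: Poisson, with activity read as expected counts per
  voxel (base 200 in normal lung — a regime in which the in-lung maximum
  is stable);
* **scatter floor**: 2 % of base activity outside the lungs.

Ground truth is defined *before* blur and noise: a voxel is functional
when its pre-degradation activity is at least 50 % of the normal-lung
mean. This stands in for the expert's manual contour of "functional lung"
and is deliberately independent of the %max machinery under test. With the
default defect multipliers (≤ 0.25) the truth is invariant to the gradient
strength, which the suite tests. When a target functional fraction is
requested, defect radii are found by bisection; auto-placed defect centers
get sub-voxel jitter so the achievable fraction moves in ~single-voxel
steps and the target is hit to within ±0.02 even on coarse grids.

`generate_cohort()` draws per-case fractions uniformly (default 0.4–0.9),
1–3 defects, and a 1-ml hot spot with probability 0.3, and generates PFT
indices linearly coupled to the realised true fraction with Gaussian noise
calibrated to a target population correlation (`coupling_for_r()`):
FEV1/FVC at r ≈ 0.8, FEV1 %pred ≈ 0.6, DLCO %pred ≈ 0.45, FVC %pred ≈ 0.3,
mirroring the typical ordering of correlations between functional volume
and spirometry in obstructive disease. Values are clipped to
physiological ranges chosen wide enough that clipping barely attenuates
the correlation (< 0.01 at the defaults).

Paired designs (same seed, with/without hot spots) are exactly comparable:
the Poisson noise uses one random substream for the hot-spot-free field
and a separate one for hot-spot-affected voxels, and the blurred hot-spot
contribution is clipped to a 3 × radius support, so the two phantoms are
voxelwise identical elsewhere.

What the phantom does **not** emulate: real airway trees and lobar
anatomy, attenuation/scatter artefacts, respiratory motion and gating,
inter-observer variability of manual contours (truth is noise-free), and
pathology beyond multiplicative focal defects. Passing the suite therefore
shows the method is implemented correctly and behaves as designed under
controlled degradations — not that a particular cutoff is clinically
optimal; on clinical images the optimal cutoff varies per patient, which
is exactly why the adaptive protocol exists.

## Numerical choices and degenerate inputs

* Voxels are wholly in or out of a mask; physical volume is count × voxel
  volume. Sub-voxel precision is not needed for %WL quantities.
* All inter-volume operations require an identical lattice
  (`assert_same_lattice`, 10⁻³ mm tolerance); nothing resamples silently.
* Cluster connectivity is 26-neighbourhood for blob detection and
  component keeping; hole filling uses 6-connectivity for the background.
* The whole-lung HU threshold is strict (`< −400`), the functional
  threshold inclusive (`≥`).
* Ties in the per-case optimal cutoff break toward the cutoff nearest
  15 %max, then toward the lower cutoff.
* Degenerate inputs error early with stage-named messages: uniform CT (no
  lung-sized component), empty WL mask, all-voxels-excluded maximum
  estimation, n < 2 Bland-Altman, zero-variance Pearson.
* Determinism: (spec, seed) fixes every phantom array bit-for-bit;
  pipeline outputs are byte-identical across reruns.

## Validation problem sizes

The shipped suite validates sweeps (nesting, monotonicity, scale
invariance) on 20 noisy phantoms at the default 64 × 64 × 48 grid; checks
`dice`/`pearson`/`bland_altman` against brute-force formula evaluation on
200 random instances each; demonstrates exact recovery (volume difference
0, Dice 1) on noiseless two-valued phantoms at every admissible cutoff;
runs the full pipeline on ten 30-case cohorts to confirm that the
cohort-optimal cutoff recovers the true functional fraction to within a
few %WL points and is stable across master seeds; and estimates the
FEV1/FVC coupling on 500 reduced-grid (32³) cohort replicates to confirm
the calibrated population correlation is recovered within n = 30 sampling
error. `scripts/acceptance.R` reruns the cohort analysis from scratch at a
given seed and writes the headline numbers as JSON.

## Known limitations

* DICOM import handles the common uncompressed explicit-VR little-endian
  single-frame case only; NIfTI-1 is the canonical interchange format.
* Inputs must be pre-aligned on one lattice; PET-to-CT registration and
  respiratory gating are out of scope.
* Airway removal is a simple top-slice-seeded region grow; on the phantom
  (which has no airway tree) it is a no-op, and on real data imperfect
  airway removal perturbs only the WL denominator, not the functional
  method under test.
* Absolute (SUV-style) quantification and per-lobe delineation are not
  implemented.
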