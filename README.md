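# vqfv — threshold-based delineation of functional lung volumes from V/Q PET/CT

Ventilation/perfusion (V/Q) PET/CT with ⁶⁸Ga-labelled tracers (Galligas for
ventilation, ⁶⁸Ga-MAA for perfusion) images regional lung function. The
*functional volume* — the ventilated or perfused part of the anatomical
lung, expressed as a percentage of the whole-lung (WL) volume — correlates
with pulmonary function tests and is useful for radiotherapy planning and
pre-surgical evaluation, but manual contouring is slow and
operator-dependent.

`vqfv` implements the standard automatic alternative and the machinery to
evaluate it:

* **Whole-lung segmentation** on CT by Hounsfield-unit thresholding
  (HU < −400) with border-air removal, largest-component selection,
  morphological closing, hole filling and optional airway removal.
* **Percentage-of-maximum delineation**: the functional mask at cutoff *c*
  is `{v ∈ WL : A(v) ≥ (c/100) · A_max}`, where the reference maximum
  `A_max` is estimated excluding focal airway-deposition "hot spots"
  (automatically, or via the operator's value/ROI), and the cutoff ladder
  is 5, 10, 15, 20, 25, 30, 40, 50 %max.
* **Adaptive protocol**: start at 15 %max and greedily try neighbouring
  cutoffs while an explicit objective improves (match a reference contour,
  or find a plateau of the volume–cutoff curve).
* **Evaluation statistics**: Dice coefficient `2|A∩B|/(|A|+|B|)`, signed
  volume difference in %WL points, Pearson correlation (two-sided t test),
  Bland–Altman bias and limits of agreement `bias ± 1.96·SD`, cohort
  summary tables and report files.
* **Digital thoracic phantoms**: paired CT + V/Q PET with known
  ground-truth functional masks — anterior–posterior activity gradient,
  focal defects, hot spots, 8 mm PSF blur, Poisson noise — plus synthetic
  PFT indices (FEV1/FVC, FEV1 %pred, DLCO %pred, FVC %pred) coupled to the
  true functional fraction at calibrated population correlations.

I/O is NIfTI-1 (via RNifti) with minimal DICOM series import; a thin CLI
(`inst/cli/vqfv.R`) exposes the pipeline stages as subcommands.

## Worked example

```r
library(vqfv)

# a phantom with 70% functional lung, default imaging degradations
ph <- generate_phantom(phantom_spec(functional_fraction = 0.7, seed = 42))

wl <- segment_lungs(ph$case$ct)           # whole lung from CT
dice(wl, ph$truth_wl)                     # 1
me <- estimate_max(ph$case$pet_vent, wl)  # hot-spot-safe reference max
sw <- threshold_sweep(ph$case$pet_vent, wl, me)
print(sw)
```

```
<threshold_sweep>
 cutoff_pct abs_threshold voxels volume_pct_wl
          5         14.95  19759      96.93387
         10         29.90  15485      75.96644
         15         44.85  14915      73.17013
         20         59.80  14747      72.34596
         25         74.75  14600      71.62480
         30         89.70  14458      70.92818
         40        119.60  14021      68.78434
         50        149.50  12951      63.53513
```

The 5 %max threshold overshoots (it scoops up the blurred defect penumbra
and lung-edge partial volume), the 10–30 %max volumes sit close to the
true functional fraction, and higher cutoffs progressively clip the
dimmer anterior lung. Scoring against the known truth:

```r
ev <- evaluate_case(sw, ph$truth_functional_vent, wl, case_id = "c1")
ev[, c("cutoff_pct", "volume_pct_wl_auto", "volume_diff", "dsc")]
best_cutoff_per_case(ev)   # 30 for this phantom
```

```
  cutoff_pct volume_pct_wl_auto volume_diff       dsc
1          5           96.93387  26.9132653 0.8387988
2         10           75.96644   5.9458399 0.9592715
3         15           73.17013   3.1495290 0.9779361
4         20           72.34596   2.3253532 0.9834597
5         25           71.62480   1.6041994 0.9878433
6         30           70.92818   0.9075746 0.9911246
7         40           68.78434  -1.2362637 0.9883367
8         50           63.53513  -6.4854788 0.9513664
```

(`volume_pct_wl_ref` is 70.02 %WL, the phantom's true functional
fraction.) At cohort level, `generate_cohort()` + `run_cohort()` +
`summarize_cohort()` produce the per-cutoff difference table, the
per-case optimal-cutoff histogram, Bland–Altman statistics and PFT
correlations, and `write_cohort_report()` writes them as deterministic
CSV tables.

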