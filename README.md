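# PEFquant

Post-segmentation analysis of pericardial effusion (PEF) on chest CT.

A pericardial effusion is abnormal fluid (conventionally > 50 mL) in the
sac surrounding the heart; when that fluid is blood (hemopericardium) the
finding is immediately life-threatening.  Given a CT volume and a binary
segmentation mask of the effusion — from a deep-learning model, a manual
reader, or the built-in phantom generator — PEFquant computes everything
that comes *after* segmentation:

* **Volumetry** — effusion volume as voxel count × voxel volume, with the
  rule-based flags *PEF present* (> 50 mL), *large PEF* (> 100 mL) and the
  composite *alert*.
* **Hemopericardium classification** — every masked voxel contributes its
  attenuation; values outside the fluid/blood window [0, 80] HU are
  discarded and the **median HU** of the remainder is compared against a
  24.5 HU cutoff (median HU > 24.5 ⇒ hemopericardium).
* **Threshold calibration** — empirical ROC curves whose candidate
  thresholds are midpoints between consecutive distinct scores (which is
  why integer-HU data yield half-integer cutoffs such as 24.5), trapezoidal
  AUC (= normalized Mann–Whitney U), and both the Youden
  (max *J* = Se + Sp − 1) and closest-top-left
  (min (1−Se)² + (1−Sp)²) operating points.
* **Accuracy and agreement statistics** — exact Clopper–Pearson binomial
  confidence intervals, Dice coefficient, Bland–Altman limits of agreement,
  two-way random-effects ICC(A,1), Pearson r², Welch t and Mann–Whitney U
  subgroup comparisons.
* **Synthetic thoracic phantoms** — chest CT volumes (trunk, lungs,
  blood pool, effusion shell, optional pleural-effusion confounder) with
  exact ground-truth masks, whose per-case attenuation and volume
  statistics follow a published clinical cohort (hemopericardium
  36.10 ± 9.72 HU vs simple effusion 19.20 ± 5.52 HU; volumes
  ≈ 198 ± 160 mL), so the entire pipeline is testable without patient
  data.

Everything reads and writes NIfTI-1/2 (`.nii` / `.nii.gz`); masks must sit
on the grid of their CT — the package never resamples silently.

## Worked example

```r
library(PEFquant)

## a 300 mL hemopericardium phantom with a 36 HU effusion
ph <- generatePhantom(phantomSpec("hemopericardium", targetVolumeMl = 300,
                                  gridShape = c(64, 64, 64),
                                  spacing = c(4, 4, 4),
                                  perCaseMeanHu = 36, seed = 4))
report <- classifyCase(ph$ct, ph$mask, caseId = "demo")
report
#> PEFReport [demo]
#>   volume: 300.0 mL (4688 voxels); median HU: 36.00 (0 filtered out)
#>   PEF > 50 mL: TRUE | large (> 100 mL): TRUE | hemopericardium (HU > 24.5): TRUE | alert: TRUE

## exact binomial CI for 97 detected out of 100 positives
clopperPearson(97, 100)
#> 97/100 = 97.00% (95% CI 91.48-99.38%)
```

The volume is within 0.1 % of the requested 300 mL (4688 voxels ×
0.064 mL), the filtered median recovers the per-case attenuation exactly,
and all three decision rules fire, so the case lands on the alert list.

The full pipeline (simulate → quantify → calibrate → evaluate) runs from
one call, or from the shell via the thin wrapper in
`inst/scripts/pefquant`:

```r
res <- runPipeline(runConfig(outDir = "run1",
                             simulate = list(nHemo = 39L, nSimple = 61L,
                                             nNegative = 0L),
                             seed = 1))
```

which writes per-case JSON reports, a cohort CSV, the ROC with both
operating points, detection/classification accuracy with exact CIs, and
the alert list — all embedding the config and seed that produced them.

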