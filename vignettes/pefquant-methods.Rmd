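---
title: "Quantifying and classifying pericardial effusion on chest CT"
author: "PEFquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying pericardial effusion on chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PEFquant)
```

## The problem

Pericardial effusion (PEF) — fluid in the sac surrounding the heart — is
conventionally diagnosed on CT when its volume exceeds 50 mL.  Two
downstream questions matter clinically: is the effusion *large*
(> 100 mL, a tamponade risk), and is it *blood* (hemopericardium)?
Segmentation models and human readers both produce binary masks; this
package implements everything that follows the mask: volumetry, the
attenuation-based blood/serous classification, the calibration of the
attenuation cutoff, and the statistics used to judge agreement and
diagnostic accuracy.

## Per-case quantification

For a mask $M$ on a CT with voxel spacing $(d_x, d_y, d_z)$ mm:

* **Volume**: $V = |M| \cdot d_x d_y d_z / 1000$ mL, exactly.  No partial
  volume modelling is attempted; the mask is the unit of truth.
* **Attenuation statistic**: collect the HU value of every mask voxel,
  keep values inside the inclusive window $[0, 80]$ HU — below 0 is fat
  or air, above 80 is calcification or contrast pooling, neither of which
  is effusion fluid — and take the **median** of the remainder.  The
  median (not the mean) makes the statistic robust to residual
  out-of-class voxels at the mask boundary.  When *no* voxel survives the
  window the median is undefined (`NA`); the hemopericardium flag is then
  FALSE, because there is no attenuation evidence of blood.
* **Decision rules** (all strict inequalities):
  PEF present $\iff V > 50$ mL; large PEF $\iff V > 100$ mL;
  hemopericardium $\iff \mathrm{median\ HU} > 24.5$; alert
  $\iff$ hemopericardium OR large PEF.

Three boundary conventions deserve a word.  The window bounds are
*inclusive* — "outside the range 0 to 80" naturally reads as $<0$ or
$>80$.  The volume comparisons are strict, so exactly 50 mL does not
count as an effusion; on real data the boundary case is measure-zero, on
phantoms it is decided and tested.  The half-integer 24.5 HU cutoff makes
equality impossible on integer-valued CTs, and the median is compared at
full float precision — rounding it first could flip a 24.4 to 24 or a
24.6 to 25 and silently change the call.  The alert combines its two
inputs with OR, the clinically conservative reading (either finding alone
warrants attention); both flags are carried per case, so a stricter AND
policy is recoverable from any report.

## Threshold calibration

The empirical ROC uses as candidate thresholds the *midpoints between
consecutive distinct sorted scores*, plus one sentinel below the minimum
and one above the maximum, with "score strictly greater than threshold"
as the positive call.  On integer-valued attenuation data this is exactly
what produces half-integer operating thresholds such as 24.5 — a
property the tests assert.  The AUC is the trapezoidal area under this
curve, which equals the Mann–Whitney $U$ statistic normalized by
$n_+ n_-$ with ties counted one half (also asserted, against the rank-sum
itself and against pROC).

Two operating-point criteria are provided: **Youden**
($\max\ Se + Sp - 1$) and **closest top-left**
($\min\ (1-Se)^2 + (1-Sp)^2$).  Ties are broken toward the smallest
threshold, which favours sensitivity — the defensible direction for a
screening alert.  For two normal score distributions the
population-optimal Youden threshold is the density-crossing point between
the class means; `binormalDensityCrossing()` solves it numerically and the
tests require the empirical threshold to converge to it.

Diagnostic proportions carry exact Clopper–Pearson intervals from Beta
quantiles — the construction that reproduces published accuracy CIs to
their printed precision — with the closed-form one-sided bounds at 0 and
$n$ successes.  A DeLong-type AUC interval is deliberately not offered:
it would suggest a precision we cannot validate without per-case clinical
data; `bootstrapAucCi()` is provided instead and labelled an
approximation.

## Agreement statistics

Dice is $2|A \cap B| / (|A| + |B|)$; two empty masks agree that nothing
is present, so that case is defined as 1 and flagged with a warning
rather than left NaN.  Bland–Altman limits of agreement are
$\bar d \pm 1.96\, s_d$ with the $n-1$ SD.  The ICC is the two-way
random-effects, absolute-agreement, single-measure form (ICC(A,1)):
absolute agreement is the right question for volumes, where a calibrated
offset between raters is still disagreement.  Its CI uses the
McGraw–Wong F construction with Satterthwaite degrees of freedom.
Subgroup comparisons report both a Welch $t$ (unequal variances assumed —
subgroup sizes and spreads differ by construction) and a Mann–Whitney
$U$, exact by enumeration when both groups have at most 8 untied
observations and a tie-corrected normal approximation with continuity
correction otherwise.

## The phantom generator

Every downstream stage is exercised on synthetic thoracic phantoms, so no
data download is ever needed.  A phantom is a deterministic function of
its `PhantomSpec` (the seed fully determines the bytes on disk):

* air background (−1000 HU), an elliptical-cylinder trunk of soft tissue
  (40 HU), two lung ellipsoids (−800 HU), and a cardiac blood-pool
  ellipsoid (45 HU, or 200 HU with contrast);
* the effusion as the shell between the heart surface and an
  outward-scaled copy of it, the scale solved by bisection so the
  truth-mask volume lands within 5 % of the requested target (on the
  default grid it lands within a fraction of a percent); an unreachable
  target raises an error naming the limiting axis;
* optionally a pleural effusion (10 HU) as a crescent around the
  posterior half of one lung, always disjoint from the truth mask — the
  confounder that sits immediately adjacent to pericardial fluid on real
  scans;
* the per-case effusion attenuation drawn once from the class
  distribution — hemopericardium 36.10 ± 9.72 HU, simple effusion
  19.20 ± 5.52 HU, with contrast/non-contrast arm-specific values when
  the contrast flag is set — then i.i.d. Gaussian voxel noise added
  globally and the volume rounded to integer HU, as scanners emit.

The ± values are interpreted as the *across-case* spread of the per-case
median, so the generator realizes them by drawing a per-case mean; the
voxel noise largely cancels in the median (the tests bound the residual
effect below 2 HU).  Cohort generation draws positive volumes from a
log-normal moment-matched to mean 198.2 / SD 159.8 mL and truncated to
[60, 900] mL — the family and bounds are modelling choices, only the
moments are cohort-anchored — negatives carry a physiological rim drawn
uniformly from [10, 40] mL, contrast is assigned to 58 % of positives
(52 % of negatives), and a pleural confounder to 25 % of cases.

Default geometry is a 128³ grid at 2 mm isotropic spacing (a 256 mm
field of view); attenuation statistics are grid-independent, so the test
suite runs most phantoms at 64³ / 4 mm and the replicate-cohort analyses
at 40³ / 6.5 mm to keep each case under a second.  The voxel noise SD
defaults to 8 HU, typical soft-tissue noise at routine dose; it is a free
parameter because per-voxel dispersion inside an effusion is not
something the cohort statistics constrain, and median-based statistics
are insensitive to it.

What the phantoms deliberately do **not** emulate: real cardiac anatomy
and motion, beam hardening and metal artifacts, post-mortem appearance
(collapsed chambers, inhomogeneous clot), or segmentation *errors* —
phantom masks are exact by construction.  Passing tests therefore
demonstrate that the quantification, calibration and statistics are
correct given a mask, not that any particular segmentation model is
accurate; mask-quality statistics (Dice, ICC, Bland–Altman) become
informative only when genuine predictions are supplied.

## The chest crop

Real hemopericardium studies are often not chest-only scans, so the CT is
first cropped to the chest.  The lung mask comes from classical image
processing — voxels below −500 HU, 6-connected components, components
touching the array border removed (that is the outside air), the two
largest retained — which on phantoms is exact and on any chest CT yields
the standard bounding box.  The crop is that bounding box dilated by a
symmetric margin (default 20 mm, converted to voxels by ceiling per
axis) and clamped to the grid; the CT and all supplied masks are sliced
identically, HU values untouched.  An empty lung mask degrades to a
warning and an uncropped pass-through rather than an error, so
abdominal-only inputs still produce a report.  Cropping at a fixed margin
is idempotent.

## Numerical conventions

* Grid compatibility: dimensions must match exactly; spacings are
  compared at a relative tolerance of 1e-5 because NIfTI stores them as
  32-bit floats.  A mismatch is always an error — the package never
  resamples silently.
* Masks are stored as unsigned 8-bit, HU volumes as int16 or float32;
  round-trips are bit-exact for integer data.
* Nonzero mask values other than 1 are coerced to 1 with a warning
  (label-valued masks are common in practice).
* HU values outside [−1100, 3100] warn but do not error: they indicate a
  scaling problem worth flagging, not a state worth refusing.
* The shell-scale bisection runs 60 halvings of a bracketed interval,
  far below voxel-count granularity.

## Simulation sizes and reproducibility

The replicate-cohort simulation behind the calibration checks uses 1,000
cohorts of 39 positives / 61 negatives; at that size the Monte-Carlo
standard error of the averaged AUC is about 0.001 and of the averaged
rates about 0.15 points.  The end-to-end phantom recovery analysis
averages 30 image-level cohorts (about one point of residual noise on
each rate).  Because the generator draws attenuation from
contrast-stratified arms, the exact expectations for those cohorts are
the corresponding mixture forms rather than the pooled two-normal
formulas; the recovery test derives both from `huClassStats()`.  Every
stochastic path is seeded, and a pipeline bundle embeds the config and
seed that produced it, so each number in it is reproducible from the
bundle alone.

## Known limitations

* The hemopericardium cutoff is calibrated on median attenuation of the
  *whole* effusion; focal clot in a serous effusion can hide below the
  median, and pericardial enhancement after contrast can push a simple
  effusion above it.  The flag should support, not replace, reading the
  images.
* The classical lung extraction assumes air-filled lungs surrounded by
  soft tissue; severe consolidation or large pneumothorax would distort
  the crop box (it would still never alter retained HU values).
* Published cohort agreement values (Dice, ICC of real reader pairs)
  require the original segmentations and are intentionally not asserted
  anywhere; the statistics battery is instead verified against
  independent re-implementations and reference packages.
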