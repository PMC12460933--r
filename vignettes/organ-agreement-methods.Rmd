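---
title: "Quantifying segmentation-method agreement for organ-level PET features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying segmentation-method agreement for organ-level PET features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organAgree)
```

## The problem

Automated CT segmentation tools can delineate dozens of anatomical
structures on a whole-body PET/CT scan in minutes. When those masks are
copied onto the PET volume to quantify organ metabolism, the question is
whether two such tools are *interchangeable*: do Volume, SUVmax, SUVpeak,
SUVmean and SUVmedian agree well enough that studies using different
segmentation software can be compared?

organAgree implements the full agreement analysis: per-structure feature
extraction from paired segmentations, mask-overlap metrics, a symmetric
relative-difference statistic, and a tiered per-structure reproducibility
classification across a cohort — together with a synthetic phantom
generator so that every stage is testable end-to-end without patient data.

## Features and their discretisation

All analysis happens on a fixed isotropic grid (2 mm by default; PET is
resampled trilinearly, masks and label volumes by nearest neighbour, so
masks stay strictly binary). World coordinates use a single RAS millimetre
convention; volumes are reoriented on load.

For a structure mask $M$ and PET image $I$ (in body-weight SUV,
$\mathrm{SUV} = C\,[\mathrm{Bq/mL}] \cdot W\,[\mathrm{g}] / D\,[\mathrm{Bq}]$):

* **Volume** $= |M| \cdot v$ where $v$ is the voxel volume (reported in mL).
* **SUVmax / SUVmean / SUVmedian**: maximum, arithmetic mean and median of
  $I$ over member voxels.
* **SUVpeak**: the highest mean of $I$ over a 1 cm$^3$ spherical
  neighbourhood positioned *inside* the mask. The sphere is the set of
  integer voxel offsets whose centre-to-centre distance is at most
  $r = (3V/4\pi)^{1/3} \approx 6.2035$ mm. Membership is decided by voxel
  centres with no partial-volume weighting, so the realised kernel volume
  only approximates 1000 mm$^3$ (984 mm$^3$ at 2 mm; within 5% at 1 mm).

Two SUVpeak policies exist in the wild: requiring full sphere containment,
or letting the sphere extend past the VOI. We require containment. This is
the only policy under which SUVpeak can be *undefined* for small or thin
structures, which is an observed and clinically reported behaviour; a
centre-only policy never fails on a non-empty mask. The location of the
best centre is deliberately not part of the contract — only the maximal
mean is (ties need no tie-breaking).

Undefined values are explicit `NA` sentinels. They propagate into the
downstream statistics by pairwise exclusion per (subject, structure,
feature) and are never imputed as zero.

## Agreement statistics

Masks are compared with the Dice similarity coefficient
$2|A\cap B|/(|A|+|B|)$ (values above 0.7 conventionally called excellent)
and the classic symmetric Hausdorff distance between boundary voxels
(6-connectivity; voxels on the volume faces count as boundary; voxel-centre
world coordinates, in mm). No percentile variant is used.

Features are compared per subject $p$ and structure $i$ with the signed
difference $\Delta = f_A - f_B$ and the symmetric relative difference

$$\Delta_{rel} = \frac{2\,|f_A - f_B|}{f_A + f_B} \times 100\%$$

bounded by 200% for non-negative features. When both sides are exactly
zero we define $\Delta_{rel} = 0$ (perfect agreement on absence) rather
than leave a 0/0.

Each (structure, feature) is classified across the cohort:

| Class    | Criterion                                |
|----------|------------------------------------------|
| High     | $\Delta_{rel} \le 10\%$ in $\ge 80\%$ of subjects |
| Moderate | $\Delta_{rel} \le 20\%$ in $\ge 80\%$ of subjects |
| Poor     | otherwise (i.e. $> 20\%$ in $> 20\%$)    |

The tiers are evaluated strictly in that precedence order, which makes
them exhaustive and disjoint even at the exact-80% boundary (where the
raw tier definitions overlap). The rule is monotone: improving any
subject's $\Delta_{rel}$ never demotes the class.

Three further rules mirror common practice:

* **Exclusion**: a subject is dropped from a structure's analysis when at
  least one method produced no segmentation; every exclusion is logged
  with subject, structure and offending method. (The alternative reading —
  exclude only when *both* methods fail — would silently compare a real
  mask against an empty one; we treat one-sided failures as
  non-comparable and keep the log auditable.)
* **SUVpeak evaluability**: SUVpeak reproducibility is assessed only when
  SUVpeak was computed for strictly more than 50% of subjects under each
  method; otherwise the class is NA and no tests are run for that cell.
* **Significance**: a two-sided paired Wilcoxon signed-rank test on the
  raw feature values, $p < 0.05$ flagged. Zero differences are dropped and
  ties mid-ranked; the null distribution is exact (computed by the shift
  algorithm over doubled ranks) for $n \le 25$ and a normal approximation
  with continuity correction above — exactness at small $n$ keeps p-values
  reproducible across platforms. Spearman's rank correlation (mid-ranks,
  via `stats::cor`) accompanies the test. No multiple-testing correction
  is applied.

## The phantom generator

`generateSubject()` builds, deterministically from (master seed, subject
index), a torso-scale phantom: geometric organs (ellipsoids and tubes —
the analysis is geometry-agnostic, so no anatomical atlas is needed) with
assigned uptake over a uniform body background, convolved with an
isotropic Gaussian point-spread function and degraded with additive
Gaussian noise. The truth masks are exact rasterizations (voxel-centre
containment); the second method's masks are derived from them by
controlled perturbations — ball dilation/erosion, rigid shifts, and
random dropout (an empty mask, exercising the exclusion rule).

The default cohort (`defaultCohortSpec()`) uses a 128 × 128 × 192 grid at
2 mm, background 0.5 SUV, organs at 1–2.5 SUV, a hot bladder-like
structure at 20 SUV, PSF FWHM 6 mm and noise SD 0.05 SUV — magnitudes in
the physiological range of FDG imaging. Per-subject variability is
emulated by ±5% size jitter and ±10% uptake jitter (without it, every
subject would be identical and rank statistics degenerate).

The deliberately constructed test case is the **hot-neighbour scenario**:
the uterus sits nominally 2 mm from the bladder surface, within the PSF's
spill-over range. Its default perturbation is a 1-voxel shift toward the
bladder. Because SUVmax is read from a single voxel, the contour moving
2 mm into the spill-over gradient changes it drastically, while SUVmean —
averaged over the whole organ — barely moves. The uterus semi-axes
(20, 20, 36 mm) were chosen large enough that a 1-voxel dilation adds a
thin shell (about a quarter of the volume), keeping the SUVmean change
under 10% while the SUVmax change exceeds 20% across the jitter range;
the 2 mm nominal gap guarantees organ shapes stay disjoint even at
maximal jitter (the generator rejects overlapping organs). Other
defaults: erosion of the small thyroid-like organ produces a large
relative volume error and pushes its mask below the 1 cm$^3$ sphere
(exercising the SUVpeak NA rule), bladder erosion produces a Poor volume
class, and the adrenal-like organ drops out of method B with probability
0.2 (exercising exclusion bookkeeping).

What the phantoms do *not* emulate: anatomical shape, attenuation/scatter
and reconstruction artefacts, lesions, pleural effusion, and PET/CT
misregistration. Passing tests therefore demonstrate that the *analysis
machinery* is correct and that the classification behaves as designed
under controlled disagreement — not that any particular pair of real
segmentation tools is interchangeable.

## Numerical choices and degenerate inputs

* Resampling maps output voxel centres to continuous input indices;
  values beyond the input extent are border-clamped. Resampling at the
  native grid is the identity (returned unchanged).
* Gaussian blur is separable with a truncated kernel ($3\sigma$)
  renormalised at the volume faces, so flat regions stay flat.
* Empty masks: Volume 0, all SUV features NA, Dice NA when both masks are
  empty (0 when only one is), Hausdorff NA when either is empty.
* All-zero difference vectors make the Wilcoxon test degenerate: reported
  as $p = 1$ with a flag, never significant.
* Constant vectors have no rank correlation: Spearman returns NA.
* Cohort regeneration, feature CSVs and summary CSVs are byte-identical
  under a fixed seed.

## Problem sizes

The test suite runs cohorts of 2–5 subjects on 50-voxel grids for unit
checks, a 50-subject miniature cohort for dropout calibration, and the
full default 30-subject cohort for the end-to-end hot-neighbour analysis;
oracle comparisons (exhaustive SUVpeak search, $O(n^2)$ Hausdorff,
sign-flip Wilcoxon enumeration) use 100 randomized cases each. The same
default 30-subject cohort is what `scripts/acceptance.R` regenerates.

## Known limitations

* Only axis-aligned (non-oblique) NIfTI volumes are supported.
* The injected dose for SUV conversion is assumed decay-corrected to
  acquisition start; no decay computation is performed.
* Hausdorff is the 100th-percentile (classic) variant; robust percentiles
  (HD95) are not implemented.
* The phantom's organs are geometric primitives; effect sizes measured on
  them transfer to real anatomy only qualitatively.
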