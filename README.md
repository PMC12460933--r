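# organAgree

Are two automated CT segmentation tools interchangeable for organ-level
PET quantification? When whole-body anatomical masks from different
software are copied onto the same PET image, the extracted imaging
biomarkers — organ Volume, SUVmax, SUVpeak, SUVmean, SUVmedian — can
differ, and features read from few voxels (SUVmax from one, SUVpeak from
a 1 cm³ sphere) are especially sensitive to contour differences near
high-uptake neighbours such as the bladder or kidneys. organAgree is an R
package for physicists and imaging scientists who need to quantify that
segmentation-method dependence per structure across a cohort.

## What it computes

For each subject, structure and method, the package extracts on a fixed
isotropic grid (2 mm default; PET resampled trilinearly, masks by nearest
neighbour):

* **Volume** (mL), **SUVmax**, **SUVmean**, **SUVmedian** over the VOI,
  with SUV_bw = C[Bq/mL] · W[g] / D[Bq];
* **SUVpeak**: the highest mean over a 1 cm³ sphere (radius
  (3V/4π)^{1/3} ≈ 6.2035 mm) fully contained in the VOI — undefined
  (`NA`) for structures too small for the sphere.

Between methods it computes the Dice coefficient and classic Hausdorff
distance of the masks, and per feature the signed difference
Δ = f_A − f_B and the symmetric relative difference

    Δrel = 2 |f_A − f_B| / (f_A + f_B) × 100%

Across the cohort every (structure, feature) is classed — High (Δrel ≤ 10%
in ≥ 80% of subjects), Moderate (≤ 20% in ≥ 80%) or Poor — alongside a
paired Wilcoxon signed-rank test (exact null for n ≤ 25), Spearman rank
correlation, and summaries of the raw differences. Subjects missing a
segmentation are excluded per structure with an audit log; SUVpeak is
only classed when defined in strictly more than 50% of subjects under
both methods.

A synthetic phantom generator (geometric organs, Gaussian PSF, noise,
controlled mask perturbation and dropout) makes the whole pipeline
testable without patient data.

## Worked example

Four phantom subjects with two organs; the second method erodes the
"ball" organ by one voxel (a ~25% volume error) while the "rod" is
segmented identically:

```r
library(organAgree)

organs <- list(
  organSpec("ball", "ellipsoid", center = c(30, 30, 34),
            semiAxes = c(16, 16, 16), uptake = 2),
  organSpec("rod", "tube", center = c(70, 66, 50),
            radius = 9, halfLength = 25, axis = 3L, uptake = 1.5))
spec <- phantomCohortSpec(
  nSubjects = 4, shape = c(50L, 50L, 54L), spacing = 2, organs = organs,
  perturbations = list(ball = perturbationSpec("erode", 1)),
  psfFwhm = 6, noiseSD = 0.05, seed = 7L)

dir <- file.path(tempdir(), "demo")
runPhantom(spec, dir)      # writes NIfTI volumes + truth.csv + manifest
runExtract(dir)            # features.csv: one row per subject/structure/method
res <- runCompare(dir)     # paired records, classification, summary grid

tab <- summaryTable(res$summary)
print(tab[tab$feature %in% c("volume_ml", "suv_mean"),
          c("structure", "feature", "n_evaluable", "prop_within_10",
            "class", "wilcoxon_p", "spearman_rs", "mean_abs_delta")],
      digits = 3, row.names = FALSE)
```

```
 structure   feature n_evaluable prop_within_10 class wilcoxon_p spearman_rs
      ball volume_ml           4              0  Poor      0.125          NA
      ball  suv_mean           4              1  High      0.125         0.8
       rod volume_ml           4              1  High      1.000          NA
       rod  suv_mean           4              1  High      1.000         1.0
 mean_abs_delta
           4.85
           0.15
           0.00
           0.00
```

The eroded ball loses ~4.9 mL on average — every subject beyond the 20%
band, hence **Poor** volume reproducibility — while its SUVmean moves by
only 0.15 SUV (**High**). The rod's features agree exactly, and the
Wilcoxon test is degenerate there (p = 1). Spearman is `NA` for volumes
here because without per-subject size jitter the volumes are constant
across this tiny cohort. `formatSummaryGrid(res$summary)` renders the
class grid:

```
| Structure | Volume | SUVmax | SUVpeak | SUVmean | SUVmedian |
| --- | --- | --- | --- | --- | --- |
| ball | ⨯ | ✔ | ✔ | ✔ | ✔ |
| rod | ✔ | ✔ | ✔ | ✔ | ✔ |
```

and the paired records carry the mask agreement: the eroded ball has mean
DSC 0.832 and median Hausdorff 2.0 mm here.

The same stages are scriptable from a shell via
`inst/cli/organagree.R` (`phantom`, `extract`, `compare`, `report`
subcommands with `--config`/`--seed`/`--spacing`/`--out` flags).

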