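#' Build the SUVpeak sphere kernel
#'
#' Collects every integer voxel offset whose centre-to-centre distance from
#' the central voxel is at most the radius of a sphere of `targetVolume`
#' mm3: r = (3 V / (4 pi))^(1/3), about 6.2035 mm for the standard 1 cm3
#' neighbourhood. Membership is decided by voxel-centre distance; no
#' partial-volume weighting, so the realised kernel volume only
#' approximates the nominal one (asserted to within 15% at 2 mm spacing).
#'
#' @param spacing isotropic voxel spacing in mm (> 0).
#' @param targetVolume nominal sphere volume in mm3 (default 1000).
#' @return A [SphereKernel-class].
#' @export
buildSphereKernel <- function(spacing, targetVolume = 1000) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  r <- (3 * targetVolume / (4 * pi))^(1 / 3)
  m <- floor(r / spacing)
  if (m < 1)
    stop("spacing ", spacing,
         " mm is too coarse: the sphere kernel degenerates to a single voxel")
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  keep <- (g$i^2 + g$j^2 + g$k^2) * spacing^2 <= r^2
  offsets <- as.matrix(g[keep, , drop = FALSE])
  dimnames(offsets) <- NULL
  storage.mode(offsets) <- "integer"
  new("SphereKernel", offsets = offsets, spacing = spacing,
      nominalVolume = targetVolume)
}

.undefinedSUV <- function() NA_real_

#' Structure volume from a mask
#'
#' Member-voxel count times voxel volume, in millilitres.
#'
#' @param mask a [LabelMask-class].
#' @return Volume in mL (0 for an empty mask).
#' @export
computeVolume <- function(mask) {
  sum(mask@membership) * voxelVolume(mask) / 1000
}

#' Per-structure SUV statistics
#'
#' `suvMax`, `suvMean` and `suvMedian` are the maximum, arithmetic mean and
#' median of the PET values over member voxels. All return `NA` (the
#' explicit UNDEFINED sentinel, excluded — never imputed — downstream) for
#' an empty mask.
#'
#' @param pet a [ScalarImage-class].
#' @param mask a [LabelMask-class] on the same grid.
#' @return A single SUV value or `NA`.
#' @name suv-statistics
NULL

#' @rdname suv-statistics
#' @export
suvMax <- function(pet, mask) {
  .stopIfGridMismatch(pet, mask)
  if (!any(mask@membership)) return(.undefinedSUV())
  max(pet@values[mask@membership])
}

#' @rdname suv-statistics
#' @export
suvMean <- function(pet, mask) {
  .stopIfGridMismatch(pet, mask)
  if (!any(mask@membership)) return(.undefinedSUV())
  mean(pet@values[mask@membership])
}

#' @rdname suv-statistics
#' @export
suvMedian <- function(pet, mask) {
  .stopIfGridMismatch(pet, mask)
  if (!any(mask@membership)) return(.undefinedSUV())
  stats::median(pet@values[mask@membership])
}

# Candidate-centre map: TRUE where every kernel offset stays inside the
# mask (the sphere is fully contained in the VOI). Computed on the cropped
# mask by intersecting shifted copies.
.containedCenters <- function(membership, offsets) {
  ok <- membership
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    if (all(o == 0L)) next
    ok <- ok & .shiftArray(membership, -o, fill = FALSE)
    if (!any(ok)) break
  }
  ok
}

#' SUVpeak: highest mean over a contained 1 cm3 sphere
#'
#' Over all candidate centres for which the whole sphere kernel lies inside
#' the mask, returns the maximum of the kernel-mean of PET values. Returns
#' `NA` when no centre achieves full containment (the structure is too
#' small or thin for the 1 cm3 sphere) — these UNDEFINED values feed the
#' evaluability rule of the agreement stage. Which centre attains the
#' maximum is not part of the contract (ties need no breaking: the max of
#' means is well-defined).
#'
#' @param pet a [ScalarImage-class].
#' @param mask a [LabelMask-class] on the same grid.
#' @param kernel a [SphereKernel-class] built for the shared grid spacing;
#'   built on the fly when omitted.
#' @return SUVpeak or `NA`.
#' @export
suvPeak <- function(pet, mask, kernel = NULL) {
  .stopIfGridMismatch(pet, mask)
  sp <- spacing(pet)
  if (max(abs(sp - sp[1])) > 1e-9)
    stop("suvPeak requires an isotropic grid")
  if (is.null(kernel)) kernel <- buildSphereKernel(sp[1])
  if (abs(kernel@spacing - sp[1]) > 1e-9)
    stop("kernel spacing (", kernel@spacing,
         " mm) does not match grid spacing (", sp[1], " mm)")
  n <- sum(mask@membership)
  if (n < nrow(kernel@offsets)) return(.undefinedSUV())
  m <- max(abs(kernel@offsets))
  cropped <- .cropToMask(pet@values, mask@membership, pad = 0L)
  if (is.null(cropped)) return(.undefinedSUV())
  centers <- .containedCenters(cropped$mask, kernel@offsets)
  if (!any(centers)) return(.undefinedSUV())
  # mean over the kernel at every voxel, by summing shifted PET copies;
  # only values at contained centres are consulted, and for those every
  # shifted read lies inside the cropped box by construction.
  acc <- array(0, dim(cropped$pet))
  for (r in seq_len(nrow(kernel@offsets)))
    acc <- acc + .shiftArray(cropped$pet, -kernel@offsets[r, ], fill = 0)
  max(acc[centers]) / nrow(kernel@offsets)
}

#' Extract all features for one subject and method
#'
#' Computes Volume, SUVmax, SUVpeak, SUVmean and SUVmedian for each
#' requested structure. Per-structure problems never abort the subject:
#' empty masks yield volume 0 with all SUV features `NA` and status
#' `"empty_mask"`; structures too small for the 1 cm3 sphere carry status
#' `"sphere_does_not_fit"` with `NA` SUVpeak only.
#'
#' @param pet a [ScalarImage-class].
#' @param masks named list of [LabelMask-class] objects aligned to `pet`.
#' @param structures structure names to extract (default: all masks),
#'   reported in deterministic (sorted) order.
#' @param subjectId,method identifiers copied into the output rows.
#' @param kernel optional pre-built [SphereKernel-class].
#' @return A data.frame with one row per structure: subject_id, structure,
#'   method, volume_ml, suv_max, suv_peak, suv_mean, suv_median, n_voxels,
#'   status.
#' @export
extractAllFeatures <- function(pet, masks, structures = names(masks),
                               subjectId = "subject", method = "A",
                               kernel = NULL) {
  structures <- sort(as.character(structures))
  if (length(structures) == 0L)
    return(data.frame(subject_id = character(), structure = character(),
                      method = character(), volume_ml = numeric(),
                      suv_max = numeric(), suv_peak = numeric(),
                      suv_mean = numeric(), suv_median = numeric(),
                      n_voxels = integer(), status = character(),
                      stringsAsFactors = FALSE))
  if (is.null(kernel) && length(structures))
    kernel <- buildSphereKernel(spacing(pet)[1])
  rows <- lapply(structures, function(s) {
    mask <- masks[[s]]
    if (is.null(mask))
      return(data.frame(subject_id = subjectId, structure = s,
                        method = method, volume_ml = NA_real_,
                        suv_max = NA_real_, suv_peak = NA_real_,
                        suv_mean = NA_real_, suv_median = NA_real_,
                        n_voxels = NA_integer_, status = "missing_mask",
                        stringsAsFactors = FALSE))
    n <- sum(mask@membership)
    vol <- computeVolume(mask)
    if (n == 0L)
      return(data.frame(subject_id = subjectId, structure = s,
                        method = method, volume_ml = 0, suv_max = NA_real_,
                        suv_peak = NA_real_, suv_mean = NA_real_,
                        suv_median = NA_real_, n_voxels = 0L,
                        status = "empty_mask", stringsAsFactors = FALSE))
    vals <- pet@values[mask@membership]
    pk <- suvPeak(pet, mask, kernel)
    data.frame(subject_id = subjectId, structure = s, method = method,
               volume_ml = vol, suv_max = max(vals), suv_peak = pk,
               suv_mean = mean(vals), suv_median = stats::median(vals),
               n_voxels = n,
               status = if (is.na(pk)) "sphere_does_not_fit" else "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE,
                              stringsAsFactors = FALSE)))
}
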