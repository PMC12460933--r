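# Synthetic PET phantom cohorts: geometric organs with assigned uptake,
# Gaussian PSF blur and noise; a second segmentation derived from the truth
# by controlled perturbation (dilate/erode/shift/dropout). Everything is
# deterministic given (master seed, subject index).

#' Specify one phantom organ
#'
#' Organs are geometric primitives (the agreement analysis under test is
#' geometry-agnostic): an ellipsoid with given centre and semi-axes, or a
#' tube (finite cylinder) along a grid axis. Uptake is the assigned mean
#' SUV inside the organ before partial-volume blur; `uptakeSD` adds
#' within-organ voxel noise. `sizeJitter`/`uptakeJitter` are per-subject
#' relative variations (uniform in +/- the fraction) emulating anatomical
#' and physiological variability across a cohort. `hot = TRUE` marks
#' high-uptake structures (bladder-like) whose neighbours are the
#' interesting test case for SUVmax.
#'
#' @param name structure name.
#' @param shape "ellipsoid" or "tube".
#' @param center world-mm centre (3-vector).
#' @param semiAxes ellipsoid semi-axes in mm (3-vector, > 0).
#' @param radius,halfLength,axis tube geometry (mm, mm, axis 1..3).
#' @param uptake mean SUV (>= 0).
#' @param uptakeSD within-organ voxel SD (SUV).
#' @param hot high-uptake neighbour flag.
#' @param sizeJitter,uptakeJitter per-subject relative variation fractions.
#' @return A validated organ spec (list).
#' @export
organSpec <- function(name, shape = c("ellipsoid", "tube"), center,
                      semiAxes = NULL, radius = NULL, halfLength = NULL,
                      axis = 3L, uptake = 1, uptakeSD = 0, hot = FALSE,
                      sizeJitter = 0, uptakeJitter = 0) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3L, all(is.finite(center)),
            uptake >= 0, uptakeSD >= 0,
            sizeJitter >= 0, sizeJitter < 1, uptakeJitter >= 0)
  if (shape == "ellipsoid") {
    stopifnot(length(semiAxes) == 3L, all(semiAxes > 0))
  } else {
    stopifnot(length(radius) == 1L, radius > 0,
              length(halfLength) == 1L, halfLength > 0, axis %in% 1:3)
  }
  structure(list(name = name, shape = shape, center = as.numeric(center),
                 semiAxes = as.numeric(semiAxes), radius = radius,
                 halfLength = halfLength, axis = as.integer(axis),
                 uptake = uptake, uptakeSD = uptakeSD, hot = hot,
                 sizeJitter = sizeJitter, uptakeJitter = uptakeJitter),
            class = "organSpec")
}

#' Specify the perturbation applied to one organ's second mask
#'
#' The second method's mask is the truth mask transformed by a
#' morphological perturbation: dilation or erosion by a ball structuring
#' element (`magnitude` = radius in voxels), a rigid shift by `magnitude`
#' voxels along `direction`, or nothing ("none"). Independently,
#' `dropoutProb` is the chance that the second method produces no
#' segmentation at all for the organ (an empty mask, feeding the exclusion
#' rule).
#'
#' @param mode "none", "dilate", "erode", "shift" or "dropout".
#' @param magnitude non-negative perturbation size in voxels.
#' @param direction integer 3-vector for shifts (default +x).
#' @param dropoutProb probability in [0, 1] of an empty second mask.
#' @return A validated perturbation spec (list).
#' @export
perturbationSpec <- function(mode = c("none", "dilate", "erode", "shift",
                                      "dropout"),
                             magnitude = 0, direction = c(1L, 0L, 0L),
                             dropoutProb = 0) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0, length(direction) == 3L,
            dropoutProb >= 0, dropoutProb <= 1)
  structure(list(mode = mode, magnitude = magnitude,
                 direction = as.integer(round(direction)),
                 dropoutProb = dropoutProb),
            class = "perturbationSpec")
}

#' Specify a phantom cohort
#'
#' @param nSubjects number of subjects (>= 1).
#' @param shape grid shape in voxels (3 ints).
#' @param spacing isotropic voxel size in mm.
#' @param organs list of [organSpec()] objects (disjoint shapes).
#' @param perturbations named list of [perturbationSpec()] per organ name;
#'   organs without an entry get "none".
#' @param background body-background uptake (SUV).
#' @param psfFwhm isotropic Gaussian PSF full width at half maximum (mm,
#'   >= 0; 0 disables blur).
#' @param noiseSD additive Gaussian noise SD (SUV, >= 0).
#' @param seed master seed; per-subject seeds are derived as
#'   (seed + 100003 * subject index) mod 2^31 so subjects are independent
#'   and reproducible in any order.
#' @return A validated cohort spec (list).
#' @export
phantomCohortSpec <- function(nSubjects, shape = c(128L, 128L, 192L),
                              spacing = 2, organs, perturbations = list(),
                              background = 0.5, psfFwhm = 6, noiseSD = 0.05,
                              seed = 42L) {
  stopifnot(nSubjects >= 1, length(shape) == 3L, all(shape >= 1),
            spacing > 0, psfFwhm >= 0, noiseSD >= 0, length(organs) >= 1)
  nm <- vapply(organs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate organ names in cohort spec")
  names(organs) <- nm
  bad <- setdiff(names(perturbations), nm)
  if (length(bad))
    stop("perturbations refer to unknown organs: ",
         paste(bad, collapse = ", "))
  structure(list(nSubjects = as.integer(nSubjects),
                 shape = as.integer(shape), spacing = spacing,
                 organs = organs, perturbations = perturbations,
                 background = background, psfFwhm = psfFwhm,
                 noiseSD = noiseSD, seed = as.integer(seed)),
            class = "phantomCohortSpec")
}

.subjectSeed <- function(masterSeed, subjectIndex) {
  as.integer((as.numeric(masterSeed) + 100003 * subjectIndex) %% 2^31)
}

# Rasterize one organ on the grid: membership by voxel-centre containment.
# Returns a logical array. Organ geometry may be jittered beforehand.
.rasterizeOrgan <- function(organ, grid) {
  member <- array(FALSE, grid@shape)
  if (organ$shape == "ellipsoid") {
    lo <- organ$center - organ$semiAxes
    hi <- organ$center + organ$semiAxes
  } else {
    ax <- organ$axis
    lo <- organ$center - organ$radius
    hi <- organ$center + organ$radius
    lo[ax] <- organ$center[ax] - organ$halfLength
    hi[ax] <- organ$center[ax] + organ$halfLength
  }
  rng <- vector("list", 3L)
  for (k in 1:3) {
    w <- .axisCoords(grid, k)
    idx <- which(w >= lo[k] - grid@spacing[k] & w <= hi[k] + grid@spacing[k])
    if (!length(idx)) return(member)
    rng[[k]] <- idx
  }
  w1 <- .axisCoords(grid, 1)[rng[[1]]]
  w2 <- .axisCoords(grid, 2)[rng[[2]]]
  w3 <- .axisCoords(grid, 3)[rng[[3]]]
  if (organ$shape == "ellipsoid") {
    q1 <- ((w1 - organ$center[1]) / organ$semiAxes[1])^2
    q2 <- ((w2 - organ$center[2]) / organ$semiAxes[2])^2
    q3 <- ((w3 - organ$center[3]) / organ$semiAxes[3])^2
    sub <- outer(outer(q1, q2, "+"), q3, "+") <= 1
  } else {
    ws <- list(w1, w2, w3)
    ax <- organ$axis
    perp <- setdiff(1:3, ax)
    r1 <- ((ws[[perp[1]]] - organ$center[perp[1]]) / organ$radius)^2
    r2 <- ((ws[[perp[2]]] - organ$center[perp[2]]) / organ$radius)^2
    along <- abs(ws[[ax]] - organ$center[ax]) <= organ$halfLength
    radial <- outer(r1, r2, "+") <= 1
    sub <- array(FALSE, c(length(w1), length(w2), length(w3)))
    # orient the radial disc and axial extent onto the right axes
    if (ax == 3L) sub <- outer(radial, along, "&")
    else if (ax == 1L) sub <- aperm(outer(radial, along, "&"), c(3, 1, 2))
    else sub <- aperm(outer(radial, along, "&"), c(1, 3, 2))
  }
  member[rng[[1]], rng[[2]], rng[[3]]] <- sub
  member
}

# Ball structuring-element offsets of integer radius r (voxel units).
.ballOffsets <- function(r) {
  r <- as.integer(round(r))
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  m <- as.matrix(g[g$i^2 + g$j^2 + g$k^2 <= r^2, , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Perturb a binary mask
#'
#' Dilation/erosion by a ball structuring element of the given radius
#' (voxels), rigid shift by `magnitude` voxels along `direction`, or
#' "dropout" (the realised empty-mask event: returns an empty mask, which
#' downstream feeds the exclusion rule). Erosion that empties the mask is
#' valid. Magnitude 0 (or mode "none") is the identity.
#'
#' @param mask a [LabelMask-class].
#' @param mode "none", "dilate", "erode", "shift" or "dropout".
#' @param magnitude non-negative integer voxels.
#' @param direction integer 3-vector for shifts.
#' @return A [LabelMask-class] on the same grid.
#' @export
perturbMask <- function(mask, mode = "none", magnitude = 0,
                        direction = c(1L, 0L, 0L)) {
  member <- mask@membership
  if (mode == "dropout")
    return(labelMask(array(FALSE, dim(member)), mask@grid, mask@structure))
  if (mode == "none" || magnitude == 0)
    return(mask)
  if (mode == "shift") {
    off <- as.integer(round(direction * magnitude))
    out <- .shiftArray(member, off, fill = FALSE)
  } else {
    offs <- .ballOffsets(magnitude)
    out <- if (mode == "dilate") array(FALSE, dim(member))
           else member
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      if (mode == "dilate")
        out <- out | .shiftArray(member, o, fill = FALSE)
      else
        out <- out & .shiftArray(member, -o, fill = FALSE)
    }
  }
  labelMask(out, mask@grid, mask@structure)
}

# Separable Gaussian blur with edge renormalisation (truncated kernel
# reweighted so flat regions stay flat up to the volume faces).
.gaussianBlur <- function(values, fwhmMM, spacingMM) {
  if (fwhmMM <= 0) return(values)
  sigma <- fwhmMM / (2 * sqrt(2 * log(2))) / spacingMM  # in voxels
  R <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-R:R)^2) / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(values)
  for (k in 1:3) {
    acc <- array(0, d)
    norm1d <- numeric(d[k])
    for (t in -R:R) {
      o <- integer(3); o[k] <- t
      acc <- acc + w[t + R + 1L] * .shiftArray(values, o, fill = 0)
      valid <- pmin(pmax(seq_len(d[k]) - t, 0L), d[k] + 1L)
      norm1d <- norm1d + w[t + R + 1L] * (valid >= 1L & valid <= d[k])
    }
    acc <- sweep(acc, k, norm1d, "/")
    values <- acc
  }
  values
}

#' Generate one phantom subject
#'
#' The truth masks (`masksA`) are exact rasterizations of the (per-subject
#' jittered) organ shapes; the PET volume is the per-organ uptake map over
#' a uniform body background, convolved with the isotropic Gaussian PSF and
#' degraded with additive Gaussian noise; `masksB` are the truth masks
#' transformed per the perturbation spec (including dropout events). Organ
#' shapes must be pairwise disjoint. Output is fully determined by
#' (master seed, subject index).
#'
#' @param spec a [phantomCohortSpec()].
#' @param subjectIndex 1-based subject index.
#' @return list(pet = [ScalarImage-class], masksA, masksB = named lists of
#'   [LabelMask-class], truth = data.frame of per-organ ground truth,
#'   labelsA, labelsB = integer label volumes, labelIds = named ids).
#' @export
generateSubject <- function(spec, subjectIndex) {
  stopifnot(inherits(spec, "phantomCohortSpec"),
            subjectIndex >= 1, subjectIndex <= spec$nSubjects)
  grid <- imageGrid(spec$shape, spacing = spec$spacing, origin = c(0, 0, 0))
  seed <- .subjectSeed(spec$seed, subjectIndex)
  set.seed(seed)
  organNames <- names(spec$organs)
  pet <- array(spec$background, grid@shape)
  masksA <- masksB <- vector("list", length(organNames))
  names(masksA) <- names(masksB) <- organNames
  labelsA <- labelsB <- array(0L, grid@shape)
  labelIds <- stats::setNames(seq_along(organNames), organNames)
  occupancy <- array(FALSE, grid@shape)
  truthRows <- list()
  for (i in seq_along(organNames)) {
    organ <- spec$organs[[i]]
    # per-subject anatomical / physiological variation
    jorgan <- organ
    jit <- 1 + stats::runif(3, -organ$sizeJitter, organ$sizeJitter)
    if (organ$shape == "ellipsoid") {
      jorgan$semiAxes <- organ$semiAxes * jit
    } else {
      jorgan$radius <- organ$radius * jit[1]
      jorgan$halfLength <- organ$halfLength * jit[2]
    }
    uptake <- organ$uptake *
      (1 + organ$uptakeJitter * stats::runif(1, -1, 1))
    member <- .rasterizeOrgan(jorgan, grid)
    if (any(member & occupancy))
      stop("organ shapes overlap: '", organ$name,
           "' intersects a previously placed organ")
    occupancy <- occupancy | member
    n <- sum(member)
    vox <- if (organ$uptakeSD > 0 && n > 0)
      uptake + stats::rnorm(n, 0, organ$uptakeSD) else rep(uptake, n)
    pet[member] <- vox
    maskA <- labelMask(member, grid, organ$name)
    pert <- spec$perturbations[[organ$name]]
    if (is.null(pert)) pert <- perturbationSpec("none")
    dropped <- stats::runif(1) < pert$dropoutProb
    maskB <- if (dropped)
      perturbMask(maskA, "dropout")
    else if (pert$mode == "dropout")   # not realised this subject
      maskA
    else
      perturbMask(maskA, pert$mode, pert$magnitude, pert$direction)
    masksA[[organ$name]] <- maskA
    masksB[[organ$name]] <- maskB
    labelsA[member] <- labelIds[[organ$name]]
    labelsB[maskB@membership] <- labelIds[[organ$name]]
    truthRows[[i]] <- data.frame(
      subject_id = sprintf("sub-%03d", subjectIndex),
      structure = organ$name,
      true_volume_ml = n * voxelVolume(grid) / 1000,
      true_mean_uptake = uptake,
      perturb_mode = if (dropped) "dropout" else pert$mode,
      perturb_magnitude = if (dropped) NA_real_ else pert$magnitude,
      empty_mask_B = !any(maskB@membership),
      stringsAsFactors = FALSE)
  }
  pet <- .gaussianBlur(pet, spec$psfFwhm, spec$spacing)
  if (spec$noiseSD > 0)
    pet <- pet + array(stats::rnorm(length(pet), 0, spec$noiseSD), dim(pet))
  list(pet = scalarImage(pet, grid, unit = "SUV_bw"),
       masksA = masksA, masksB = masksB,
       truth = do.call(rbind, truthRows),
       labelsA = labelsA, labelsB = labelsB, labelIds = labelIds,
       grid = grid, seed = seed)
}

#' Write a phantom cohort to disk
#'
#' Lays out `n` subjects in the directory scheme the pipeline consumes:
#' \preformatted{
#' cohort/
#'   structure_map.yaml     # structure -> label ids per method
#'   manifest.csv           # subject_id, file paths, per-subject seed
#'   truth.csv              # per-(subject, organ) ground truth
#'   sub-001/pet.nii.gz  seg_A.nii.gz  seg_B.nii.gz
#' }
#' PET volumes are stored as float32, label volumes as integers.
#' Regeneration with the same spec and master seed is deterministic.
#'
#' @param spec a [phantomCohortSpec()].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly; also written as
#'   `manifest.csv`.
#' @export
generateCohort <- function(spec, dir) {
  stopifnot(inherits(spec, "phantomCohortSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create cohort directory: ", dir)
  organNames <- names(spec$organs)
  smap <- list(structures = lapply(stats::setNames(
    seq_along(organNames), organNames),
    function(i) list(A = i, B = i)))
  yaml::write_yaml(smap, file.path(dir, "structure_map.yaml"))
  manifest <- list(); truths <- list()
  for (s in seq_len(spec$nSubjects)) {
    sid <- sprintf("sub-%03d", s)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    subj <- generateSubject(spec, s)
    petPath <- file.path(sdir, "pet.nii.gz")
    segA <- file.path(sdir, "seg_A.nii.gz")
    segB <- file.path(sdir, "seg_B.nii.gz")
    writeVolume(subj$pet, petPath, datatype = "float")
    writeVolume(subj$labelsA, segA, grid = subj$grid)
    writeVolume(subj$labelsB, segB, grid = subj$grid)
    manifest[[s]] <- data.frame(subject_id = sid, pet = petPath,
                                seg_A = segA, seg_B = segB,
                                seed = subj$seed, stringsAsFactors = FALSE)
    truths[[s]] <- subj$truth
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, truths), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' The default phantom cohort
#'
#' A torso-scale phantom on a 128 x 128 x 192 grid at 2 mm: body
#' background 0.5 SUV; six soft-tissue organs with uptake 1-2.5 SUV; a hot
#' bladder-like structure at 20 SUV with the uterus placed 4 mm from it
#' (the hot-neighbour scenario: a 1-voxel outward move of the uterus
#' contour picks up intense bladder spill-over, destabilising SUVmax but
#' barely moving SUVmean); PSF FWHM 6 mm; noise SD 0.05 SUV. The default
#' perturbations emulate typical inter-algorithm disagreement: contour
#' shifts for large well-behaved organs, erosion of the small thyroid-like
#' structure (large relative volume error; its eroded mask also stops
#' fitting the 1 cm3 SUVpeak sphere), a shift of the uterus toward the
#' bladder, and a 20% segmentation-dropout rate for the adrenal-like
#' structure to exercise the exclusion rule.
#'
#' @param nSubjects cohort size (default 30).
#' @param seed master seed (default 42).
#' @return A [phantomCohortSpec()].
#' @export
defaultCohortSpec <- function(nSubjects = 30, seed = 42L) {
  organs <- list(
    organSpec("liver", "ellipsoid", center = c(70, 120, 240),
              semiAxes = c(45, 35, 30), uptake = 2.5, uptakeSD = 0.1,
              sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("spleen", "ellipsoid", center = c(195, 120, 245),
              semiAxes = c(20, 18, 16), uptake = 1.8, uptakeSD = 0.1,
              sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("muscle", "tube", center = c(195, 195, 150),
              radius = 10, halfLength = 60, axis = 3L, uptake = 1,
              uptakeSD = 0.1, sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("bladder", "ellipsoid", center = c(128, 128, 100),
              semiAxes = c(20, 20, 18), uptake = 20, uptakeSD = 0.5,
              hot = TRUE, sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("uterus", "ellipsoid", center = c(128, 128, 156),
              semiAxes = c(20, 20, 36), uptake = 1.2, uptakeSD = 0.1,
              sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("thyroid", "ellipsoid", center = c(128, 128, 330),
              semiAxes = c(8, 8, 10), uptake = 2, uptakeSD = 0.1,
              sizeJitter = 0.05, uptakeJitter = 0.1),
    organSpec("adrenal", "ellipsoid", center = c(70, 120, 180),
              semiAxes = c(7, 6, 12), uptake = 1.2, uptakeSD = 0.1,
              sizeJitter = 0.05, uptakeJitter = 0.1))
  perturbations <- list(
    liver = perturbationSpec("shift", 1, c(1L, 0L, 0L)),
    muscle = perturbationSpec("shift", 1, c(0L, 1L, 0L)),
    bladder = perturbationSpec("erode", 1),
    uterus = perturbationSpec("shift", 1, c(0L, 0L, -1L)),
    thyroid = perturbationSpec("erode", 1),
    adrenal = perturbationSpec("shift", 1, c(1L, 0L, 0L),
                               dropoutProb = 0.2))
  phantomCohortSpec(nSubjects = nSubjects, organs = organs,
                    perturbations = perturbations, seed = seed)
}
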