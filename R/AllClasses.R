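#' @import methods
NULL

.SUV_UNITS <- c("SUV_bw", "Bq_per_mL", "unitless")

#' ImageGrid: geometry of a 3-D voxel grid
#'
#' Describes where a voxel array lives in world space: the number of voxels
#' per axis, the voxel spacing in millimetres, and the world coordinates (mm)
#' of the centre of the first voxel. All internal maths uses one fixed
#' axis convention (RAS: +x right, +y anterior, +z superior); readers
#' reorient volumes on load so that downstream overlap metrics compare
#' like with like.
#'
#' @slot shape integer(3), voxels per axis (each >= 1).
#' @slot spacing numeric(3), mm per voxel along each axis (each > 0).
#' @slot origin numeric(3), world coordinates (mm) of the first voxel centre.
#' @exportClass ImageGrid
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive reals")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite reals")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageGrid
#'
#' @param shape integer(3) voxels per axis.
#' @param spacing numeric(3) or scalar, mm per voxel.
#' @param origin numeric(3), world mm of the first voxel centre.
#' @return An [ImageGrid-class] object.
#' @export
imageGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' ScalarImage: a scalar voxel volume with grid metadata
#'
#' A 3-D array of finite real values (PET uptake in SUV or Bq/mL, or any
#' scalar field) together with its [ImageGrid-class] and a unit tag.
#'
#' @slot grid the [ImageGrid-class].
#' @slot values 3-D numeric array, dimensions equal to the grid shape.
#' @slot unit one of "SUV_bw", "Bq_per_mL", "unitless".
#' @exportClass ScalarImage
setClass("ScalarImage",
  representation(grid = "ImageGrid", values = "array", unit = "character"),
  prototype(unit = "unitless"))

setValidity("ScalarImage", function(object) {
  msg <- character()
  if (!identical(dim(object@values), object@grid@shape))
    msg <- c(msg, "value array dimensions must equal grid shape")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@unit) != 1L || !object@unit %in% .SUV_UNITS)
    msg <- c(msg, sprintf("unit must be one of %s",
                          paste(.SUV_UNITS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ScalarImage
#'
#' @param values 3-D numeric array.
#' @param grid an [ImageGrid-class]; defaults to unit spacing at the origin.
#' @param unit unit tag ("SUV_bw", "Bq_per_mL" or "unitless").
#' @return A [ScalarImage-class].
#' @export
scalarImage <- function(values, grid = NULL, unit = "unitless") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("expected 3-D volume, got ", length(dim(values)), "-D data")
  if (is.null(grid)) grid <- imageGrid(dim(values))
  storage.mode(values) <- "double"
  new("ScalarImage", grid = grid, values = values, unit = unit)
}

#' LabelMask: a binary structure mask on a grid
#'
#' Membership of one anatomical structure (volume of interest), stored as a
#' logical array on an [ImageGrid-class]. Feature extraction requires the
#' mask grid to be identical to the PET grid it is paired with.
#'
#' @slot grid the [ImageGrid-class].
#' @slot membership 3-D logical array.
#' @slot structure structure name.
#' @exportClass LabelMask
setClass("LabelMask",
  representation(grid = "ImageGrid", membership = "array",
                 structure = "character"),
  prototype(structure = ""))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!identical(dim(object@membership), object@grid@shape))
    msg <- c(msg, "membership dimensions must equal grid shape")
  if (!is.logical(object@membership) || anyNA(object@membership))
    msg <- c(msg, "membership must be strictly binary (logical, no NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param membership 3-D logical (or 0/1) array.
#' @param grid an [ImageGrid-class]; defaults to unit spacing.
#' @param structure structure name.
#' @return A [LabelMask-class].
#' @export
labelMask <- function(membership, grid = NULL, structure = "") {
  membership <- as.array(membership)
  if (length(dim(membership)) != 3L)
    stop("expected 3-D mask, got ", length(dim(membership)), "-D data")
  if (!is.logical(membership)) {
    if (!all(membership %in% c(0, 1)))
      stop("mask values must be strictly binary")
    membership <- array(membership != 0, dim(membership))
  }
  if (is.null(grid)) grid <- imageGrid(dim(membership))
  new("LabelMask", grid = grid, membership = membership,
      structure = structure)
}

#' SphereKernel: voxel offsets of a fixed-volume spherical neighbourhood
#'
#' The set of integer voxel offsets whose centre-to-centre distance from a
#' central voxel does not exceed the radius of a sphere of the nominal
#' volume (1 cm3 by default). Used for SUVpeak.
#'
#' @slot offsets integer matrix, one row per offset (3 columns).
#' @slot spacing isotropic voxel spacing (mm) the kernel was built for.
#' @slot nominalVolume target sphere volume in mm3.
#' @exportClass SphereKernel
setClass("SphereKernel",
  representation(offsets = "matrix", spacing = "numeric",
                 nominalVolume = "numeric"))

setValidity("SphereKernel", function(object) {
  msg <- character()
  if (ncol(object@offsets) != 3L)
    msg <- c(msg, "offsets must have 3 columns")
  o <- object@offsets
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (!setequal(key(o), key(-o)))
    msg <- c(msg, "offset set must be symmetric under negation")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: per-structure reproducibility summary of a cohort
#'
#' Result container of [summarizeCohort()]: one row per (structure, feature)
#' with the evaluable subject count, the proportions of subjects whose
#' symmetric relative difference falls within 10% and 20%, the
#' reproducibility class, the paired Wilcoxon p-value, the Spearman rank
#' correlation, and summaries of the raw differences.
#'
#' @slot table the per-(structure, feature) data.frame.
#' @slot globals per-feature cohort-level counts (structures with p < 0.05,
#'   Spearman range).
#' @slot rule the classification rule used (list with thresholds and
#'   proportions).
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(table = "data.frame", globals = "data.frame", rule = "list"))
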