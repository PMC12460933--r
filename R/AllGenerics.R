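#' Grid accessors
#'
#' Accessors for grid geometry: `gridOf` returns the [ImageGrid-class],
#' `spacing` the voxel spacing in mm, `origin` the world coordinates of the
#' first voxel centre, `voxelVolume` the volume of one voxel in mm3, and
#' `voxelData` the underlying array (numeric for images, logical for masks).
#'
#' @param x an ImageGrid, ScalarImage or LabelMask.
#' @return See description; `spacing`/`origin` are numeric(3).
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname grid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname grid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname grid-accessors
#' @export
setGeneric("imageUnit", function(x) standardGeneric("imageUnit"))

#' @rdname grid-accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))

#' Resample an image or mask onto an isotropic grid
#'
#' @param x a [ScalarImage-class] or [LabelMask-class].
#' @param targetSpacing positive isotropic voxel size in mm (default 2).
#' @return An object of the same class on the resampled grid.
#' @export
setGeneric("resampleToIsotropic",
  function(x, targetSpacing = 2) standardGeneric("resampleToIsotropic"))

setMethod("gridOf", "ScalarImage", function(x) x@grid)
setMethod("gridOf", "LabelMask", function(x) x@grid)
setMethod("gridOf", "ImageGrid", function(x) x)

setMethod("spacing", "ImageGrid", function(x) x@spacing)
setMethod("spacing", "ScalarImage", function(x) x@grid@spacing)
setMethod("spacing", "LabelMask", function(x) x@grid@spacing)
setMethod("spacing", "SphereKernel", function(x) x@spacing)

setMethod("origin", "ImageGrid", function(x) x@origin)
setMethod("origin", "ScalarImage", function(x) x@grid@origin)
setMethod("origin", "LabelMask", function(x) x@grid@origin)

setMethod("voxelVolume", "ImageGrid", function(x) prod(x@spacing))
setMethod("voxelVolume", "ScalarImage", function(x) prod(x@grid@spacing))
setMethod("voxelVolume", "LabelMask", function(x) prod(x@grid@spacing))

setMethod("voxelData", "ScalarImage", function(x) x@values)
setMethod("voxelData", "LabelMask", function(x) x@membership)

setMethod("imageUnit", "ScalarImage", function(x) x@unit)
setMethod("structureName", "LabelMask", function(x) x@structure)

setMethod("dim", "ScalarImage", function(x) x@grid@shape)
setMethod("dim", "LabelMask", function(x) x@grid@shape)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "ScalarImage", function(object) {
  v <- object@values
  cat(sprintf("ScalarImage [%s]: %s voxels @ %s mm, range [%.4g, %.4g]\n",
              object@unit, paste(dim(v), collapse = "x"),
              paste(format(object@grid@spacing), collapse = "x"),
              min(v), max(v)))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask '%s': %d / %d member voxels (%.3g mL)\n",
              object@structure, sum(object@membership),
              length(object@membership),
              sum(object@membership) * prod(object@grid@spacing) / 1000))
})

setMethod("show", "SphereKernel", function(object) {
  cat(sprintf(
    "SphereKernel: %d offsets @ %.3g mm spacing (%.1f mm3, nominal %.0f mm3)\n",
    nrow(object@offsets), object@spacing,
    nrow(object@offsets) * object@spacing^3, object@nominalVolume))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d structures x %d features\n",
              length(unique(object@table$structure)),
              length(unique(object@table$feature))))
  cat(sprintf("  rule: High dRel<=%g%% in >=%g%%; Moderate dRel<=%g%% in >=%g%%\n",
              object@rule$high_threshold, 100 * object@rule$high_proportion,
              object@rule$moderate_threshold,
              100 * object@rule$moderate_proportion))
  cls <- table(object@table$class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

#' Accessors for CohortSummary
#'
#' `summaryTable` returns the per-(structure, feature) table;
#' `summaryGlobals` the per-feature cohort-level counts.
#'
#' @param x a [CohortSummary-class].
#' @return A data.frame.
#' @name summary-accessors
NULL

#' @rdname summary-accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))
#' @rdname summary-accessors
#' @export
setGeneric("summaryGlobals", function(x) standardGeneric("summaryGlobals"))

setMethod("summaryTable", "CohortSummary", function(x) x@table)
setMethod("summaryGlobals", "CohortSummary", function(x) x@globals)
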