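# Resampling onto a fixed isotropic grid. Grids are axis-aligned in the
# package's RAS convention, so interpolation is separable: each output voxel
# centre maps to a continuous input index per axis.

.targetGrid <- function(grid, targetSpacing) {
  extent <- (grid@shape - 1L) * grid@spacing
  shape <- pmax(1L, as.integer(ceiling(extent / targetSpacing - 1e-9)) + 1L)
  imageGrid(shape, spacing = rep(targetSpacing, 3L), origin = grid@origin)
}

# Continuous (1-based) input index of each output voxel centre per axis,
# clamped to the input extent (border replication beyond the last centre).
.sourceIndex <- function(inGrid, outGrid, axis) {
  w <- .axisCoords(outGrid, axis)
  idx <- (w - inGrid@origin[axis]) / inGrid@spacing[axis] + 1
  pmin(pmax(idx, 1), inGrid@shape[axis])
}

.isIdentityResample <- function(inGrid, outGrid, tol = 1e-9) {
  identical(inGrid@shape, outGrid@shape) &&
    all(abs(inGrid@spacing - outGrid@spacing) <= tol) &&
    all(abs(inGrid@origin - outGrid@origin) <= tol)
}

# Trilinear interpolation (scalar images).
.resampleTrilinear <- function(values, inGrid, outGrid) {
  ix <- lapply(1:3, function(k) .sourceIndex(inGrid, outGrid, k))
  lo <- lapply(seq_along(ix), function(k)
    pmin(pmax(floor(ix[[k]]), 1), inGrid@shape[k]))
  hi <- lapply(seq_along(ix), function(k) pmin(lo[[k]] + 1, inGrid@shape[k]))
  fr <- lapply(seq_along(ix), function(k) ix[[k]] - lo[[k]])
  sh <- outGrid@shape
  out <- array(0, sh)
  # accumulate the 8 corner contributions with outer-product weights
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    i1 <- if (cx) hi[[1]] else lo[[1]]
    i2 <- if (cy) hi[[2]] else lo[[2]]
    i3 <- if (cz) hi[[3]] else lo[[3]]
    w1 <- if (cx) fr[[1]] else 1 - fr[[1]]
    w2 <- if (cy) fr[[2]] else 1 - fr[[2]]
    w3 <- if (cz) fr[[3]] else 1 - fr[[3]]
    corner <- values[as.integer(i1), as.integer(i2), as.integer(i3),
                     drop = FALSE]
    w <- outer(outer(w1, w2), w3)
    dim(w) <- sh
    out <- out + w * corner
  }
  out
}

# Nearest-neighbour interpolation (masks and label volumes).
.resampleNearest <- function(values, inGrid, outGrid) {
  ix <- lapply(1:3, function(k) {
    i <- round(.sourceIndex(inGrid, outGrid, k))
    as.integer(pmin(pmax(i, 1), inGrid@shape[k]))
  })
  values[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' @describeIn resampleToIsotropic trilinear interpolation of voxel values.
#' @export
setMethod("resampleToIsotropic", "ScalarImage", function(x, targetSpacing = 2) {
  if (!is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be positive")
  outGrid <- .targetGrid(x@grid, targetSpacing)
  if (.isIdentityResample(x@grid, outGrid)) return(x)
  scalarImage(.resampleTrilinear(x@values, x@grid, outGrid), outGrid,
              unit = x@unit)
})

#' @describeIn resampleToIsotropic nearest-neighbour interpolation; the
#'   output stays strictly binary.
#' @export
setMethod("resampleToIsotropic", "LabelMask", function(x, targetSpacing = 2) {
  if (!is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be positive")
  outGrid <- .targetGrid(x@grid, targetSpacing)
  if (.isIdentityResample(x@grid, outGrid)) return(x)
  labelMask(.resampleNearest(x@membership, x@grid, outGrid), outGrid,
            structure = x@structure)
})

#' Resample an integer label volume to an isotropic grid
#'
#' Nearest-neighbour resampling of a multi-label segmentation volume.
#'
#' @param labels integer 3-D array.
#' @param grid the input [ImageGrid-class].
#' @param targetSpacing positive isotropic voxel size in mm.
#' @return list(labels = integer array, grid = output [ImageGrid-class]).
#' @export
resampleLabels <- function(labels, grid, targetSpacing = 2) {
  if (!is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be positive")
  outGrid <- .targetGrid(grid, targetSpacing)
  if (.isIdentityResample(grid, outGrid))
    return(list(labels = labels, grid = grid))
  out <- .resampleNearest(labels, grid, outGrid)
  storage.mode(out) <- "integer"
  list(labels = out, grid = outGrid)
}
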