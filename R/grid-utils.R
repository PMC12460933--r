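# Internal grid helpers shared by the I/O, feature and phantom code.

.sameGrid <- function(a, b, tol = 1e-6) {
  ga <- gridOf(a); gb <- gridOf(b)
  identical(ga@shape, gb@shape) &&
    all(abs(ga@spacing - gb@spacing) <= tol) &&
    all(abs(ga@origin - gb@origin) <= tol)
}

.stopIfGridMismatch <- function(pet, mask) {
  if (!.sameGrid(pet, mask))
    stop("PET image and mask must share one grid (shape, spacing, origin)")
}

# World coordinates (mm) of voxel centres along one axis.
.axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

# World coordinates of a set of voxel indices (matrix n x 3, 1-based).
.worldCoords <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

# Shift a 3-D array by an integer voxel offset, filling vacated voxels.
.shiftArray <- function(a, offset, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- offset[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o)
    } else {
      dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Bounding box (list of index ranges) of TRUE voxels, padded by `pad` voxels
# and clipped to the array. NULL for an empty mask.
.maskBoundingBox <- function(membership, pad = 0L) {
  d <- dim(membership)
  rng <- vector("list", 3L)
  for (k in 1:3) {
    proj <- apply(membership, k, any)
    if (!any(proj)) return(NULL)
    w <- which(proj)
    rng[[k]] <- max(1L, min(w) - pad):min(d[k], max(w) + pad)
  }
  rng
}

# Crop a PET array and mask array to the mask bounding box (plus padding).
# Returns list(pet=, mask=) or NULL when the mask is empty.
.cropToMask <- function(petValues, membership, pad = 0L) {
  bb <- .maskBoundingBox(membership, pad)
  if (is.null(bb)) return(NULL)
  list(pet = petValues[bb[[1]], bb[[2]], bb[[3]], drop = FALSE],
       mask = membership[bb[[1]], bb[[2]], bb[[3]], drop = FALSE],
       box = bb)
}
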