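#' Dice similarity coefficient of two masks
#'
#' 2|A intersect B| / (|A| + |B|). In cohort reports a DSC above 0.7 is
#' conventionally called excellent. Two empty masks have an undefined
#' overlap and return `NA`.
#'
#' @param maskA,maskB [LabelMask-class] objects on a shared grid.
#' @return DSC in [0, 1], or `NA` when both masks are empty.
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!.sameGrid(maskA, maskB))
    stop("diceCoefficient requires masks on a shared grid")
  nA <- sum(maskA@membership)
  nB <- sum(maskB@membership)
  if (nA + nB == 0L) return(NA_real_)
  2 * sum(maskA@membership & maskB@membership) / (nA + nB)
}

# Boundary voxels: members with at least one non-member 6-neighbour;
# voxels on the volume faces count as boundary.
.boundaryVoxels <- function(membership) {
  if (!any(membership)) return(membership)
  interior <- membership
  for (k in 1:3) for (s in c(-1L, 1L)) {
    o <- integer(3); o[k] <- s
    interior <- interior & .shiftArray(membership, o, fill = FALSE)
    if (!any(interior)) break
  }
  membership & !interior
}

# Directed Hausdorff: max over points of A of the min distance to B.
# Chunked so the pairwise distance matrix stays small.
.directedHausdorff <- function(ptsA, ptsB, chunk = 512L) {
  worst <- 0
  nB <- nrow(ptsB)
  for (start in seq(1L, nrow(ptsA), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(ptsA))
    a <- ptsA[idx, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(ptsB^2), "+") - 2 * tcrossprod(a, ptsB)
    worst <- max(worst, max(apply(d2, 1L, min)))
  }
  sqrt(max(worst, 0))
}

#' Classic Hausdorff distance between two masks
#'
#' Symmetric (100th-percentile) Hausdorff distance between the two
#' boundary-voxel sets, in mm, using voxel-centre world coordinates.
#' Boundaries use 6-connectivity; member voxels on the volume faces count
#' as boundary. Returns `NA` when either mask is empty.
#'
#' @param maskA,maskB [LabelMask-class] objects on a shared grid.
#' @return Hausdorff distance in mm, or `NA`.
#' @export
hausdorffDistance <- function(maskA, maskB) {
  if (!.sameGrid(maskA, maskB))
    stop("hausdorffDistance requires masks on a shared grid")
  if (!any(maskA@membership) || !any(maskB@membership)) return(NA_real_)
  grid <- gridOf(maskA)
  pts <- function(membership) {
    # crop (pad 1) so boundary extraction touches only the local box
    bb <- .maskBoundingBox(membership, pad = 1L)
    sub <- membership[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
    idx <- which(.boundaryVoxels(sub), arr.ind = TRUE)
    idx <- sweep(idx, 2L, vapply(bb, function(r) r[1] - 1L, integer(1)), "+")
    .worldCoords(grid, idx)
  }
  ptsA <- pts(maskA@membership)
  ptsB <- pts(maskB@membership)
  max(.directedHausdorff(ptsA, ptsB), .directedHausdorff(ptsB, ptsA))
}
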