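# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use different code paths from the implementation
# (index gathering and O(n^2) scans instead of array shifting).

# Exhaustive SUVpeak: every voxel is a candidate centre; the full sphere
# must lie inside the mask; report the best kernel mean. Works by linear
# index gathering (a different code path from the shift-based
# implementation).
bruteForceSuvPeak <- function(pet, mask, kernel) {
  d <- dim(voxelData(pet))
  offs <- kernel@offsets
  member <- voxelData(mask)
  vals <- voxelData(pet)
  centers <- which(array(TRUE, d), arr.ind = TRUE)
  inb <- rep(TRUE, nrow(centers))
  for (k in 1:3)
    inb <- inb & centers[, k] + min(offs[, k]) >= 1L &
      centers[, k] + max(offs[, k]) <= d[k]
  if (!any(inb)) return(NA_real_)
  lin0 <- (centers[inb, 1] + d[1] * (centers[inb, 2] - 1L) +
             d[1] * d[2] * (centers[inb, 3] - 1L))
  offLin <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  linMat <- outer(lin0, offLin, "+")
  nOff <- nrow(offs)
  contained <- rowSums(matrix(member[linMat], ncol = nOff)) == nOff
  if (!any(contained)) return(NA_real_)
  max(rowMeans(matrix(vals[linMat], ncol = nOff)[contained, ,
                                                 drop = FALSE]))
}

# O(n^2) Hausdorff over boundary points extracted by explicit neighbour
# checking in a triple loop-free but index-based way.
bruteForceBoundary <- function(member) {
  d <- dim(member)
  idx <- which(member, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    onFace <- any(p == 1L) || any(p == d)
    if (onFace) { keep[r] <- TRUE; next }
    for (k in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[k] <- q[k] + s
      if (!member[q[1], q[2], q[3]]) { keep[r] <- TRUE; break }
    }
  }
  idx[keep, , drop = FALSE]
}

bruteForceHausdorff <- function(maskA, maskB) {
  g <- gridOf(maskA)
  toWorld <- function(idx)
    sweep(sweep(idx - 1, 2, g@spacing, "*"), 2, g@origin, "+")
  pa <- toWorld(bruteForceBoundary(voxelData(maskA)))
  pb <- toWorld(bruteForceBoundary(voxelData(maskB)))
  directed <- function(x, y) {
    worst <- 0
    for (r in seq_len(nrow(x))) {
      dmin <- min(sqrt(colSums((t(y) - x[r, ])^2)))
      worst <- max(worst, dmin)
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Exhaustive two-sided paired Wilcoxon: enumerate all 2^n sign
# assignments of the mid-ranked |d| and apply the same two-sided rule
# p = min(1, 2 min(P(W <= w), P(W >= w))).
enumWilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  lower <- mean(Ws <= W + 1e-12)
  upper <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(lower, upper))
}

# Mid-rank Pearson correlation computed from first principles.
midRankPearson <- function(a, b) {
  midrank <- function(x) {
    n <- length(x)
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    r
  }
  ra <- midrank(a); rb <- midrank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Random blob mask: union of a few small random boxes, <= maxVox voxels.
randomSmallMask <- function(grid, maxVox = 200, allowEmpty = FALSE) {
  d <- grid@shape
  member <- array(FALSE, d)
  for (i in seq_len(sample(1:3, 1))) {
    lo <- pmax(1L, sapply(d, function(k) sample.int(k, 1)) - sample(0:3, 3, TRUE))
    hi <- pmin(d, lo + sample(0:3, 3, TRUE))
    member[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  if (!allowEmpty && !any(member)) member[1, 1, 1] <- TRUE
  if (sum(member) > maxVox) {
    keep <- which(member)
    member[keep[-seq_len(maxVox)]] <- FALSE
  }
  labelMask(member, grid)
}

# Small solid-ellipsoid phantom with a hotspot, on an isotropic grid.
hotspotPhantom <- function(n = 24, spacing = 2, hotspot = TRUE) {
  grid <- imageGrid(c(n, n, n), spacing)
  ctr <- (n - 1) * spacing / 2
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  w <- sweep(idx - 1, 2, rep(spacing, 3), "*")
  r2 <- rowSums(sweep(w, 2, rep(ctr, 3), "-")^2)
  member <- array(r2 <= (0.42 * n * spacing)^2, c(n, n, n))
  vals <- array(1 + 0.1 * sin(seq_len(n^3) / 7), c(n, n, n))
  if (hotspot) {
    hs <- exp(-r2 / (2 * (0.12 * n * spacing)^2))
    vals <- vals + 8 * array(hs, c(n, n, n))
  }
  list(pet = scalarImage(vals, grid, "SUV_bw"),
       mask = labelMask(member, grid))
}

# Tiny two-organ cohort spec for fast end-to-end tests.
tinyCohortSpec <- function(nSubjects = 2, seed = 11L, psfFwhm = 0,
                           noiseSD = 0, perturbations = list(),
                           uptakeSD = 0, sizeJitter = 0, uptakeJitter = 0) {
  organs <- list(
    organSpec("ball", "ellipsoid", center = c(30, 30, 34),
              semiAxes = c(16, 16, 16), uptake = 2, uptakeSD = uptakeSD,
              sizeJitter = sizeJitter, uptakeJitter = uptakeJitter),
    organSpec("rod", "tube", center = c(70, 66, 50),
              radius = 9, halfLength = 25, axis = 3L, uptake = 1.5,
              uptakeSD = uptakeSD, sizeJitter = sizeJitter,
              uptakeJitter = uptakeJitter))
  phantomCohortSpec(nSubjects = nSubjects, shape = c(50L, 50L, 54L),
                    spacing = 2, organs = organs,
                    perturbations = perturbations, psfFwhm = psfFwhm,
                    noiseSD = noiseSD, seed = seed)
}
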