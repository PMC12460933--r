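test_that("sphere kernel matches brute-force integer-point counts", {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)   # ~6.2035 mm

  k1 <- buildSphereKernel(1)
  expect_lt(abs(nrow(k1@offsets) * 1 - 1000) / 1000, 0.05)

  k2 <- buildSphereKernel(2)
  g <- expand.grid(i = -4:4, j = -4:4, k = -4:4)
  expected <- sum(4 * (g$i^2 + g$j^2 + g$k^2) <= r^2)
  expect_identical(nrow(k2@offsets), as.integer(expected))
  expect_lt(abs(nrow(k2@offsets) * 8 - 1000) / 1000, 0.15)

  # symmetric under negation
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(k2@offsets), key(-k2@offsets))

  expect_error(buildSphereKernel(15), "coarse")
})

test_that("volume, SUVmax/mean/median match brute-force accumulation", {
  grid <- imageGrid(c(8L, 8L, 8L), 2)
  empty <- labelMask(array(FALSE, c(8, 8, 8)), grid)
  expect_identical(computeVolume(empty), 0)
  pet0 <- scalarImage(array(3, c(8, 8, 8)), grid, "SUV_bw")
  expect_true(is.na(suvMax(pet0, empty)))
  expect_true(is.na(suvMean(pet0, empty)))
  expect_true(is.na(suvMedian(pet0, empty)))

  # 125 voxels at 2 mm = 1 mL
  m <- array(FALSE, c(8, 8, 8)); m[1:5, 1:5, 1:5] <- TRUE
  expect_equal(computeVolume(labelMask(m, grid)), 1.0)

  # known 4-voxel values
  m4 <- array(FALSE, c(8, 8, 8)); m4[1:4, 1, 1] <- TRUE
  p4 <- array(0, c(8, 8, 8)); p4[1:4, 1, 1] <- c(1, 2, 3, 10)
  mask4 <- labelMask(m4, grid)
  pet4 <- scalarImage(p4, grid, "SUV_bw")
  expect_equal(suvMean(pet4, mask4), 4.0)
  expect_equal(suvMedian(pet4, mask4), 2.5)
  expect_equal(suvMax(pet4, mask4), 10)

  # random phantoms against an independent voxel loop
  set.seed(33)
  for (i in 1:5) {
    mask <- randomSmallMask(grid)
    pet <- scalarImage(array(runif(512, 0, 20), c(8, 8, 8)), grid, "SUV_bw")
    acc <- c()
    for (v in which(voxelData(mask))) acc <- c(acc, voxelData(pet)[v])
    expect_equal(suvMax(pet, mask), max(acc))
    expect_equal(suvMean(pet, mask), mean(acc))
    expect_equal(suvMedian(pet, mask), median(acc))
    expect_equal(computeVolume(mask), length(acc) * 8 / 1000)
  }

  other <- scalarImage(array(1, c(8, 8, 9)), imageGrid(c(8L, 8L, 9L), 2))
  expect_error(suvMax(other, mask4), "grid")
})

test_that("suvPeak equals exhaustive containment search and is <= suvMax", {
  kernel <- buildSphereKernel(2)

  # uniform PET over a large solid mask -> the uniform value
  ph <- hotspotPhantom(20, hotspot = FALSE)
  uni <- scalarImage(array(2, dim(voxelData(ph$pet))), gridOf(ph$pet),
                     "SUV_bw")
  expect_equal(suvPeak(uni, ph$mask, kernel), 2.0)

  # fewer mask voxels than the kernel -> undefined
  tiny <- array(FALSE, c(20, 20, 20)); tiny[1:3, 1:3, 1:3] <- TRUE
  expect_true(is.na(suvPeak(uni, labelMask(tiny, gridOf(uni)), kernel)))

  # blurred hotspot phantom vs brute force over every centre
  ph2 <- hotspotPhantom(20)
  pk <- suvPeak(ph2$pet, ph2$mask, kernel)
  expect_equal(pk, bruteForceSuvPeak(ph2$pet, ph2$mask, kernel),
               tolerance = 1e-12)
  expect_lte(pk, suvMax(ph2$pet, ph2$mask))
})

test_that("SUV features scale linearly with the image and volume is additive", {
  set.seed(44)
  ph <- hotspotPhantom(18)
  kernel <- buildSphereKernel(2)
  scaled <- scalarImage(voxelData(ph$pet) * 3.5, gridOf(ph$pet), "SUV_bw")
  expect_equal(suvMax(scaled, ph$mask), 3.5 * suvMax(ph$pet, ph$mask))
  expect_equal(suvMean(scaled, ph$mask), 3.5 * suvMean(ph$pet, ph$mask))
  expect_equal(suvMedian(scaled, ph$mask), 3.5 * suvMedian(ph$pet, ph$mask))
  expect_equal(suvPeak(scaled, ph$mask, kernel),
               3.5 * suvPeak(ph$pet, ph$mask, kernel))

  # SUV features ignore voxels outside the mask
  outside <- voxelData(ph$pet)
  outside[!voxelData(ph$mask)] <- outside[!voxelData(ph$mask)] + 50
  pet2 <- scalarImage(outside, gridOf(ph$pet), "SUV_bw")
  expect_equal(suvMax(pet2, ph$mask), suvMax(ph$pet, ph$mask))
  expect_equal(suvMean(pet2, ph$mask), suvMean(ph$pet, ph$mask))

  # volume additivity over disjoint masks
  grid <- imageGrid(c(10L, 10L, 10L), 2)
  a <- array(FALSE, c(10, 10, 10)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[7:9, , ] <- TRUE
  expect_equal(computeVolume(labelMask(a | b, grid)),
               computeVolume(labelMask(a, grid)) +
                 computeVolume(labelMask(b, grid)))
})

test_that("ordering invariants hold on random non-empty masks", {
  set.seed(55)
  grid <- imageGrid(c(9L, 9L, 9L), 2)
  for (i in 1:20) {
    mask <- randomSmallMask(grid)
    pet <- scalarImage(array(rnorm(729, 5, 2)^2, c(9, 9, 9)), grid,
                       "SUV_bw")
    vals <- voxelData(pet)[voxelData(mask)]
    expect_lte(min(vals), suvMedian(pet, mask))
    expect_lte(suvMedian(pet, mask), suvMax(pet, mask))
    expect_lte(suvMean(pet, mask), suvMax(pet, mask))
  }
})

test_that("extractAllFeatures is consistent with individual operations", {
  ph <- hotspotPhantom(20)
  kernel <- buildSphereKernel(2)
  small <- array(FALSE, dim(voxelData(ph$pet))); small[1:2, 1:2, 1:2] <- TRUE
  masks <- list(blob = ph$mask,
                crumb = labelMask(small, gridOf(ph$pet), "crumb"),
                void = labelMask(array(FALSE, dim(voxelData(ph$pet))),
                                 gridOf(ph$pet), "void"))
  tab <- extractAllFeatures(ph$pet, masks, subjectId = "s1", method = "A",
                            kernel = kernel)
  expect_identical(tab$structure, sort(names(masks)))

  blob <- tab[tab$structure == "blob", ]
  expect_equal(blob$volume_ml, computeVolume(ph$mask))
  expect_equal(blob$suv_max, suvMax(ph$pet, ph$mask))
  expect_equal(blob$suv_peak, suvPeak(ph$pet, ph$mask, kernel))
  expect_equal(blob$suv_mean, suvMean(ph$pet, ph$mask))
  expect_equal(blob$suv_median, suvMedian(ph$pet, ph$mask))
  expect_identical(blob$status, "ok")

  crumb <- tab[tab$structure == "crumb", ]
  expect_true(is.na(crumb$suv_peak))
  expect_false(is.na(crumb$suv_max))
  expect_identical(crumb$status, "sphere_does_not_fit")

  void <- tab[tab$structure == "void", ]
  expect_identical(void$status, "empty_mask")
  expect_equal(void$volume_ml, 0)
  expect_true(all(is.na(void[c("suv_max", "suv_peak", "suv_mean",
                               "suv_median")])))

  expect_identical(nrow(extractAllFeatures(ph$pet, masks,
                                           structures = character())), 0L)
})
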