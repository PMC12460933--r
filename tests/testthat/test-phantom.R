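test_that("subject generation is deterministic and recovers parameters", {
  spec <- tinyCohortSpec(nSubjects = 2, seed = 123L)
  s1 <- generateSubject(spec, 1)
  s2 <- generateSubject(spec, 1)
  expect_identical(voxelData(s1$pet), voxelData(s2$pet))
  expect_identical(voxelData(s1$masksA$ball), voxelData(s2$masksA$ball))
  expect_identical(s1$truth, s2$truth)
  # with anatomical variability enabled, different subjects differ
  jspec <- tinyCohortSpec(nSubjects = 2, seed = 123L, sizeJitter = 0.05)
  expect_false(identical(voxelData(generateSubject(jspec, 2)$pet),
                         voxelData(generateSubject(jspec, 1)$pet)))

  # no perturbation, blur or noise: masks agree and uptake is exact
  expect_equal(diceCoefficient(s1$masksA$ball, s1$masksB$ball), 1.0)
  expect_equal(suvMean(s1$pet, s1$masksA$ball), 2.0)
  expect_equal(suvMax(s1$pet, s1$masksA$rod), 1.5)
  expect_equal(computeVolume(s1$masksA$ball),
               s1$truth$true_volume_ml[s1$truth$structure == "ball"])
})

test_that("rasterized ellipsoid volume approaches the analytic volume", {
  spec <- phantomCohortSpec(
    nSubjects = 1, shape = c(30L, 30L, 30L), spacing = 2,
    organs = list(organSpec("orb", "ellipsoid", center = c(28, 28, 28),
                            semiAxes = c(10, 10, 10), uptake = 1)),
    psfFwhm = 0, noiseSD = 0, seed = 5L)
  s <- generateSubject(spec, 1)
  vol <- computeVolume(s$masksA$orb)
  expect_lt(abs(vol - 4.18879) / 4.18879, 0.05)
})

test_that("overlapping organ shapes are rejected", {
  spec <- phantomCohortSpec(
    nSubjects = 1, shape = c(30L, 30L, 30L), spacing = 2,
    organs = list(
      organSpec("a", "ellipsoid", center = c(28, 28, 28),
                semiAxes = c(10, 10, 10), uptake = 1),
      organSpec("b", "ellipsoid", center = c(34, 28, 28),
                semiAxes = c(10, 10, 10), uptake = 2)),
    psfFwhm = 0, noiseSD = 0, seed = 5L)
  expect_error(generateSubject(spec, 1), "overlap")
})

test_that("perturbations behave as morphological operations", {
  grid <- imageGrid(c(20L, 20L, 20L), 2)
  cube <- array(FALSE, c(20, 20, 20)); cube[5:14, 5:14, 5:14] <- TRUE
  mask <- labelMask(cube, grid, "cube")

  expect_identical(perturbMask(mask, "dilate", 0), mask)
  expect_identical(perturbMask(mask, "none", 3), mask)

  # axis shift of an n-cube: DSC = (n-1)/n in closed form
  shifted <- perturbMask(mask, "shift", 1, c(1L, 0L, 0L))
  expect_equal(computeVolume(shifted), computeVolume(mask))
  expect_equal(diceCoefficient(mask, shifted), 9 / 10)

  dil <- perturbMask(mask, "dilate", 1)
  expect_gt(computeVolume(dil), computeVolume(mask))
  expect_lt(diceCoefficient(mask, dil), 1)
  expect_true(all(voxelData(dil)[voxelData(mask)]))   # superset

  ero <- perturbMask(mask, "erode", 1)
  expect_lt(computeVolume(ero), computeVolume(mask))
  expect_true(all(voxelData(mask)[voxelData(ero)]))   # subset
  # morphological opening is anti-extensive
  opened <- perturbMask(perturbMask(mask, "erode", 1), "dilate", 1)
  expect_true(all(voxelData(mask)[voxelData(opened)]))

  # erosion may empty a thin mask entirely; that is a valid empty mask
  thin <- array(FALSE, c(20, 20, 20)); thin[5:14, 5:14, 7] <- TRUE
  expect_identical(sum(voxelData(perturbMask(labelMask(thin, grid),
                                             "erode", 1))), 0L)
  expect_identical(sum(voxelData(perturbMask(mask, "dropout"))), 0L)
})

test_that("perturbation magnitude controls disagreement monotonically", {
  specFor <- function(mag) tinyCohortSpec(
    nSubjects = 3, seed = 31L,
    perturbations = list(ball = perturbationSpec(
      if (mag == 0) "none" else "erode", mag)))
  medDice <- medDrel <- numeric(3)
  for (m in 0:2) {
    spec <- specFor(m)
    dsc <- drel <- c()
    for (i in seq_len(spec$nSubjects)) {
      s <- generateSubject(spec, i)
      dsc <- c(dsc, diceCoefficient(s$masksA$ball, s$masksB$ball))
      va <- computeVolume(s$masksA$ball); vb <- computeVolume(s$masksB$ball)
      drel <- c(drel, 200 * abs(va - vb) / (va + vb))
    }
    medDice[m + 1] <- median(dsc); medDrel[m + 1] <- median(drel)
  }
  expect_true(all(diff(medDice) < 0))
  expect_true(all(diff(medDrel) > 0))
})

test_that("dropout events across a cohort stay in the binomial range", {
  spec <- tinyCohortSpec(
    nSubjects = 50, seed = 77L,
    perturbations = list(ball = perturbationSpec("dropout",
                                                 dropoutProb = 0.2)))
  events <- 0L
  for (i in 1:50) {
    s <- generateSubject(spec, i)
    events <- events + !any(voxelData(s$masksB$ball))
    stopifnot(any(voxelData(s$masksB$rod)))
  }
  expect_gte(events, qbinom(0.005, 50, 0.2))
  expect_lte(events, qbinom(0.995, 50, 0.2))
})

test_that("hot-neighbour contours destabilise SUVmax but not SUVmean", {
  # default configuration: 1-voxel dilation of the organ abutting the hot
  # bladder-like structure
  spec <- defaultCohortSpec(nSubjects = 1)
  s <- generateSubject(spec, 1)
  u <- s$masksA$uterus
  dil <- perturbMask(u, "dilate", 1)
  maxChange <- abs(suvMax(s$pet, dil) - suvMax(s$pet, u)) / suvMax(s$pet, u)
  meanChange <- abs(suvMean(s$pet, dil) - suvMean(s$pet, u)) /
    suvMean(s$pet, u)
  expect_gt(maxChange, 0.2)
  expect_lt(meanChange, 0.1)
})
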