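test_that("write/read round-trip preserves values and grid metadata", {
  set.seed(101)
  grid <- imageGrid(c(4L, 4L, 4L), spacing = c(2, 2, 2),
                    origin = c(5, -3, 10))
  img <- scalarImage(array(rnorm(64), c(4, 4, 4)), grid, unit = "SUV_bw")
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(img, f)
  back <- readVolume(f, unit = "SUV_bw")
  expect_false(back$isLabel)
  expect_identical(voxelData(back$image), voxelData(img))
  expect_equal(spacing(back$image), spacing(img), tolerance = 1e-6)
  expect_equal(origin(back$image), origin(img), tolerance = 1e-6)

  # voxel sum is preserved for a synthetic phantom across a round trip
  ph <- hotspotPhantom(16)
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$pet, f2)
  expect_identical(sum(voxelData(readVolume(f2)$image)),
                   sum(voxelData(ph$pet)))
})

test_that("label volumes round-trip as integers and 2-D input errors", {
  labels <- array(0L, c(5, 5, 5))
  labels[2:3, 2:3, 2:3] <- 4L
  grid <- imageGrid(c(5L, 5L, 5L), 2)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(labels, f, grid = grid)
  back <- readVolume(f)
  expect_true(back$isLabel)
  expect_identical(back$labels, labels)

  f2d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1.5, 4, 4)), f2d)
  expect_error(readVolume(f2d), "3-D")
  expect_error(readVolume(tempfile(fileext = ".nii")), "no such file")
})

test_that("extractStructureMask takes unions of label ids", {
  labels <- array(0L, c(6, 6, 6))
  labels[1:2, 1, 1] <- 3L          # 2 voxels of id 3
  labels[4, 4, 1:5] <- 4L          # 5 voxels of id 4
  labels[6, 6, 6] <- 9L
  grid <- imageGrid(c(6L, 6L, 6L), 2)

  empty <- extractStructureMask(array(0L, c(6, 6, 6)), "none", c(1L), grid)
  expect_identical(sum(voxelData(empty)), 0L)

  both <- extractStructureMask(labels, "organ", c(3L, 4L), grid)
  expect_identical(sum(voxelData(both)), 7L)
  expect_identical(structureName(both), "organ")

  # union count equals the sum of per-id counts for disjoint ids
  perId <- vapply(c(3L, 4L), function(id)
    sum(extractStructureMask(labels, "x", id, grid)@membership), integer(1))
  expect_identical(sum(voxelData(both)), sum(perId))

  expect_error(extractStructureMask(labels, "organ", integer()), "non-empty")
})

test_that("activity to SUV conversion follows the body-weight formula", {
  grid <- imageGrid(c(3L, 3L, 3L), 2)
  img <- scalarImage(array(5000, c(3, 3, 3)), grid, unit = "Bq_per_mL")
  suv <- activityToSUV(img, weightKg = 70, doseMBq = 250)
  expect_equal(voxelData(suv)[1], 1.4)   # 5000 * 70000 / 2.5e8
  expect_identical(imageUnit(suv), "SUV_bw")

  # pass-through for images already in SUV
  expect_identical(activityToSUV(suv), suv)
  expect_error(activityToSUV(img), "weight")

  # linear in concentration and weight, inverse-linear in dose
  set.seed(7)
  vals <- array(runif(27, 100, 9000), c(3, 3, 3))
  raw <- scalarImage(vals, grid, unit = "Bq_per_mL")
  base <- voxelData(activityToSUV(raw, 60, 200))
  expect_equal(voxelData(activityToSUV(scalarImage(vals * 3, grid,
                                                   "Bq_per_mL"), 60, 200)),
               base * 3)
  expect_equal(voxelData(activityToSUV(raw, 120, 200)), base * 2)
  expect_equal(voxelData(activityToSUV(raw, 60, 400)), base / 2)
})

test_that("structure maps parse with per-method ids and validate", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("structures:",
               "  liver: {A: [3], B: [5]}",
               "  kidneys: {A: [5, 6], B: [7, 8]}",
               "  spleen: [2]"), f)
  smap <- readStructureMap(f)
  expect_named(smap, c("liver", "kidneys", "spleen"))
  expect_identical(smap$liver$B, 5L)
  expect_identical(smap$kidneys$A, c(5L, 6L))
  expect_identical(smap$spleen$A, smap$spleen$B)

  bad <- tempfile(fileext = ".yaml")
  writeLines("structures: {}", bad)
  expect_error(readStructureMap(bad), "empty")
})
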