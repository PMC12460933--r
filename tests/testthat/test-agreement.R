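featRow <- function(volume = 10, smax = 5, speak = 4, smean = 3,
                    smedian = 2.8) {
  data.frame(volume_ml = volume, suv_max = smax, suv_peak = speak,
             suv_mean = smean, suv_median = smedian)
}

test_that("computeDeltas reproduces the symmetric relative difference", {
  d <- computeDeltas(featRow(), featRow())
  expect_true(all(d$delta == 0))
  expect_true(all(d$delta_rel == 0))

  d2 <- computeDeltas(featRow(volume = 110), featRow(volume = 90))
  row <- d2[d2$feature == "volume_ml", ]
  expect_equal(row$delta, 20)
  expect_equal(row$delta_rel, 20.0)

  # one-sided absence is the formula's 200% limit
  d3 <- computeDeltas(featRow(smax = 7), featRow(smax = 0))
  expect_equal(d3$delta_rel[d3$feature == "suv_max"], 200)

  # both zero -> perfect agreement on absence
  d4 <- computeDeltas(featRow(volume = 0), featRow(volume = 0))
  expect_equal(d4$delta_rel[d4$feature == "volume_ml"], 0)

  # undefined propagates
  d5 <- computeDeltas(featRow(speak = NA), featRow())
  expect_true(is.na(d5$delta[d5$feature == "suv_peak"]))
  expect_true(is.na(d5$delta_rel[d5$feature == "suv_peak"]))

  # symmetric in magnitude, antisymmetric in sign
  a <- featRow(volume = 132, smax = 9.5); b <- featRow(volume = 87, smax = 3)
  ab <- computeDeltas(a, b); ba <- computeDeltas(b, a)
  expect_equal(ab$delta_rel, ba$delta_rel)
  expect_equal(ab$delta, -ba$delta)
})

test_that("classification applies the tier precedence at exact boundaries", {
  expect_identical(classifyStructure(rep(5, 12)), "High")
  # 75% <= 10 but 85% <= 20 -> Moderate
  v <- c(rep(8, 15), rep(15, 2), rep(25, 3))
  expect_identical(classifyStructure(v), "Moderate")
  # 25% above 20 -> Poor
  expect_identical(classifyStructure(c(rep(5, 15), rep(30, 5))), "Poor")
  # exactly 80% within 10% -> High under the stated precedence
  boundary <- c(rep(9, 8), 50, 60)
  expect_equal(mean(boundary <= 10), 0.8)
  expect_identical(classifyStructure(boundary), "High")
  # exactly 80% within 20% (but not 10%) -> Moderate
  expect_identical(classifyStructure(c(rep(15, 8), 50, 60)), "Moderate")
  expect_true(is.na(classifyStructure(numeric())))
  expect_true(is.na(classifyStructure(c(NA_real_, NA_real_))))
})

test_that("classification is monotone: improving a value never demotes", {
  set.seed(77)
  rank <- c(High = 1, Moderate = 2, Poor = 3)
  for (i in 1:50) {
    v <- runif(sample(5:15, 1), 0, 60)
    before <- classifyStructure(v)
    j <- sample(seq_along(v), 1)
    v[j] <- v[j] * runif(1)
    expect_lte(rank[[classifyStructure(v)]], rank[[before]])
  }
})

test_that("SUVpeak evaluability needs strictly more than half per method", {
  rec <- function(nDef_A, nDef_B, n = 20) {
    data.frame(suv_peak_A = c(rep(1, nDef_A), rep(NA, n - nDef_A)),
               suv_peak_B = c(rep(1, nDef_B), rep(NA, n - nDef_B)))
  }
  expect_true(suvPeakEvaluable(rec(20, 20)))
  expect_false(suvPeakEvaluable(rec(10, 20)))   # exactly 50% under A
  expect_false(suvPeakEvaluable(rec(20, 10)))
  expect_true(suvPeakEvaluable(rec(11, 11)))    # 11/20 in both
  expect_false(suvPeakEvaluable(rec(0, 0, 0)[0, ]))
})

test_that("the exclusion rule drops and logs subjects missing one mask", {
  rec <- data.frame(
    subject_id = c("s1", "s2", "s3", "s1", "s2"),
    structure = c("liver", "liver", "liver", "spleen", "spleen"),
    n_voxels_A = c(100L, 0L, 90L, 50L, 60L),
    n_voxels_B = c(110L, 80L, 0L, 55L, 0L))
  out <- suppressMessages(excludeMissing(rec))
  expect_identical(nrow(out), 2L)
  excl <- attr(out, "exclusions")
  expect_identical(nrow(excl), 3L)
  expect_setequal(excl$subject_id, c("s2", "s3", "s2"))
  expect_identical(excl$method[excl$subject_id == "s2" &
                                 excl$structure == "liver"], "A")
  expect_message(excludeMissing(rec), "no segmentation")

  clean <- rec[c(1, 4), ]
  expect_identical(nrow(suppressMessages(excludeMissing(clean))), 2L)
})
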