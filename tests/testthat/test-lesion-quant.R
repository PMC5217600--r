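# Gaussian smoothing, relative-maximum thresholding, volumetry.

test_that("3x3 Gaussian smoothing is normalized and local", {
  # constant slice is unchanged
  expect_equal(smooth_slice(matrix(5, 10, 10)), matrix(5, 10, 10))
  # a single impulse spreads over a 3x3 footprint that sums to its value
  imp <- matrix(0, 9, 9); imp[5, 5] <- 2
  sm <- smooth_slice(imp)
  expect_equal(sum(sm), 2)
  expect_true(all(sm[abs(row(sm) - 5) > 1 | abs(col(sm) - 5) > 1] == 0))
  expect_gt(sm[5, 5], sm[5, 6])
  expect_error(smooth_slice(matrix(1, 2, 2)), "3 x 3")
})

test_that("threshold selects the bright class at 75% of the slice max", {
  sl <- matrix(60, 12, 12); sl[4:6, 4:6] <- 100
  m <- threshold_relmax(sl)
  expect_identical(sum(m), 9L)                 # 60 < 75: background out
  expect_true(all(m[4:6, 4:6]))
  # uniform nonzero slice: every pixel equals the max, all selected
  expect_true(all(threshold_relmax(matrix(3, 5, 5))))
  # zero-max slice: empty mask, no exception
  expect_false(any(threshold_relmax(matrix(0, 5, 5))))
})

test_that("lesion masks match the planted truth (Dice > 0.95)", {
  vol <- make_lesion_phantom(40, 20, 1, 0.1, seed = 6)
  res <- lesion_volume(vol)
  tm <- attr(vol, "truth_mask")
  dice <- 2 * sum(res$masks & tm) / (sum(res$masks) + sum(tm))
  expect_gt(dice, 0.95)
})

test_that("volume is the slice-area sum times thickness, exactly", {
  # noise-free slices with planted bright blocks of 200 / 300 / 100 px
  mk <- function(npx) {
    sl <- matrix(10, 32, 32)
    if (npx > 0) sl[seq_len(npx)] <- 100
    sl
  }
  vol <- volume_image(array(c(mk(200), mk(300), mk(100)), c(32, 32, 3)),
                      slice_thickness = 1, pixel_pitch = 0.1)
  res <- lesion_volume(vol)
  # the summation identity is exact; the areas themselves sit within a
  # one-pixel boundary ring of the planted blocks (edge smoothing)
  expect_equal(res$total_volume, sum(res$per_slice_area) * 1)
  expect_equal(res$per_slice_area, c(2, 3, 1), tolerance = 0.06)
  # exact linearity in slice thickness
  vol3 <- vol; vol3$slice_thickness <- 3
  expect_equal(lesion_volume(vol3)$total_volume, 3 * res$total_volume)
  # single TTC slice of measured area A gives 3A at the 3-mm thickness
  one <- volume_image(mk(150), slice_thickness = 3, pixel_pitch = 0.1,
                      modality = "TTC-like")
  r1 <- infarct_volume(one)
  expect_equal(r1$total_volume, 3 * r1$per_slice_area)
  expect_equal(r1$per_slice_area, 1.5, tolerance = 0.06)
})

test_that("the relative threshold makes volumes scale-invariant", {
  vol <- make_lesion_phantom(25, 7, 3, 0.1, modality = "TTC-like", seed = 3)
  scaled <- vol; scaled$slices <- vol$slices * 4.2
  expect_equal(lesion_volume(vol)$total_volume,
               lesion_volume(scaled)$total_volume)
})

test_that("planted volumes are recovered across the working range", {
  # TTC geometry (7 x 3 mm slices) keeps every cross-section resolvable
  for (v in c(10, 32, 40.1, 47, 63.7)) {
    ph <- make_lesion_phantom(v, 7, 3, 0.1, modality = "TTC-like",
                              seed = 31)
    got <- infarct_volume(ph)$total_volume
    expect_equal(got, attr(ph, "planted_volume_mm3"), tolerance = 0.1)
  }
  # MRI geometry at the paper-like 20 x 1 mm stack
  for (v in c(40.1, 63.7)) {
    ph <- make_lesion_phantom(v, 20, 1, 0.1, seed = 32)
    expect_equal(lesion_volume(ph)$total_volume,
                 attr(ph, "planted_volume_mm3"), tolerance = 0.1)
  }
})

test_that("infarct_volume guards the modality", {
  vol <- make_lesion_phantom(20, 7, 3, 0.1, seed = 2)  # MRI-like
  expect_error(infarct_volume(vol), "TTC")
})
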