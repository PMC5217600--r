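# Baseline normalization, perfusion masks, areas, occlusion check.

flow_of <- function(cbf, pitch = 0.0273, bin_time = NA_real_) {
  structure(list(cbf = cbf, valid = !is.na(cbf),
                 clipped = matrix(FALSE, nrow(cbf), ncol(cbf)),
                 bin_time = bin_time, pixel_pitch = pitch,
                 exposure = 5e-3, beta = 1),
            class = "flow_map")
}

test_that("normalization is identity on baseline and linear in flow", {
  base <- flow_of(matrix(200, 16, 16))
  nm <- normalize_to_baseline(base, base)
  expect_true(all(nm$N[nm$valid] == 1))
  dbl <- flow_of(matrix(400, 16, 16))
  expect_true(all(normalize_to_baseline(dbl, base)$N == 2))
  # near-zero baseline pixels are guarded out
  b2 <- matrix(200, 16, 16); b2[1, 1] <- 0.1
  nm2 <- normalize_to_baseline(dbl, flow_of(b2))
  expect_false(nm2$valid[1, 1])
  expect_error(normalize_to_baseline(dbl, flow_of(matrix(NA_real_, 16, 16))),
               "no valid"
  )
})

test_that("reduction mask uses a strict 50% threshold in the hemisphere", {
  N <- matrix(1, 8, 8)
  N[1, 1] <- 0.49; N[1, 2] <- 0.51; N[1, 3] <- 0.5   # strict boundary
  N[5, 8] <- 0.2                                      # contralateral
  hemi <- hemisphere_mask(c(8, 8), "left")
  B <- reduction_mask(nmap_of(N), hemi)$B
  expect_true(B[1, 1])
  expect_false(B[1, 2])
  expect_false(B[1, 3])       # N = 0.5 exactly is excluded
  expect_false(B[5, 8])       # outside the hemisphere
  expect_identical(sum(B), 1L)
  # baseline map: all-zero mask
  expect_identical(sum(reduction_mask(nmap_of(matrix(1, 8, 8)), hemi)$B), 0L)
})

test_that("enhancement mask is strict and monotone in its threshold", {
  N <- matrix(1, 10, 10)
  N[2:3, 2:3] <- 1.5
  hemi <- matrix(TRUE, 10, 10)
  expect_identical(sum(enhancement_mask(nmap_of(N), hemi, 1.2)$B), 4L)
  expect_identical(sum(enhancement_mask(nmap_of(matrix(1, 4, 4)),
                                        matrix(TRUE, 4, 4))$B), 0L)
  areas <- vapply(c(1.05, 1.2, 1.35, 1.49, 1.5),
                  function(th) sum(enhancement_mask(nmap_of(N), hemi,
                                                    th)$B),
                  integer(1))
  expect_true(all(diff(areas) <= 0))
  expect_identical(areas[5], 0L)  # N = 1.5 at threshold 1.5: strict
})

test_that("mask area is pixel count times pitch squared", {
  B <- matrix(FALSE, 20, 20); B[1:10, 1:10] <- TRUE
  expect_equal(mask_area(B, 0.01), 100 * 1e-4)
  expect_identical(mask_area(matrix(FALSE, 4, 4), 0.5), 0)
  # exact linearity in count, quadratic in pitch
  expect_equal(mask_area(B, 0.02), 4 * mask_area(B, 0.01))
  B2 <- B; B2[11:12, 1:10] <- TRUE
  expect_equal(mask_area(B2, 0.01), mask_area(B, 0.01) + 20 * 1e-4)
})

test_that("occlusion success demands an over-85% regional decrease", {
  roi <- matrix(FALSE, 6, 6); roi[3:4, 3:4] <- TRUE
  expect_true(occlusion_success(nmap_of(matrix(0.10, 6, 6)), roi))
  expect_false(occlusion_success(nmap_of(matrix(0.50, 6, 6)), roi))
  expect_false(occlusion_success(nmap_of(matrix(0.15, 6, 6)), roi))  # strict
  expect_error(occlusion_success(nmap_of(matrix(1, 6, 6)),
                                 matrix(FALSE, 6, 6)),
               "no valid")
})

test_that("area series track the growth curve and flag the endpoint", {
  # noise-free synthetic flow maps: baseline 100, disc drops to 20
  pitch <- 0.1
  mk <- function(r) {
    cbf <- matrix(100, 40, 40)
    if (r > 0) {
      D2 <- outer((1:40 - 20)^2, (1:40 - 10)^2, "+")
      cbf[D2 <= r^2] <- 20
    }
    flow_of(cbf, pitch)
  }
  hemi <- hemisphere_mask(c(40, 40), "left")
  flows <- lapply(c(0, 3, 5, 7), mk)
  ser <- area_time_series(flows, mk(0), hemi, times = c(1, 5, 10, 15),
                          pixel_pitch = pitch)
  expect_true(all(diff(ser$cbf50$areas) >= 0))     # monotone growth
  expect_identical(ser$cbf50$areas[1], 0)          # static baseline bin
  expect_identical(attr(ser, "endpoint"), 4L)
  expect_true(all(ser$cbfplus$areas == 0))
  # CBF_50 and CBF_+ pixel sets are disjoint by construction
  nm <- normalize_to_baseline(mk(6), mk(0))
  red <- reduction_mask(nm, hemi)$B
  enh <- enhancement_mask(nm, hemi, 1.2)$B
  expect_identical(sum(red & enh), 0L)
  expect_error(area_time_series(flows, mk(0), hemi, times = c(5, 1, 10, 15),
                                pixel_pitch = pitch),
               "ordered")
  p <- tempfile(fileext = ".csv"); on.exit(unlink(p))
  write_area_series(ser, p)
  expect_equal(utils::read.csv(p)$cbf50_mm2, ser$cbf50$areas)
})

test_that("occlusion phantom normalizes to the planted flow levels", {
  # rendered end-to-end at a shallow (70% reduction) core
  # region size and frame count chosen so the regional plateau estimate
  # (grains x frames) resolves a 10% check with margin
  cfg <- scenario_config(image_shape = c(256L, 256L),
                         target_area_15min = 6,
                         occlusion_flow_fraction = 0.3,
                         frames_per_bin = 24L, seed = 14)
  beta_w <- calibrate_beta(cfg, window = 7)
  bins <- render_time_bins(cfg, c(0, 15))
  ph <- attr(bins[[2]], "phantom")
  f0 <- contrast_to_flow(spatial_contrast(flatfield_correct(bins[[1]])),
                         beta = beta_w)
  f1 <- contrast_to_flow(spatial_contrast(flatfield_correct(bins[[2]])),
                         beta = beta_w)
  nm <- normalize_to_baseline(f1, f0)
  # interior plateaus, away from the window-blurred disc boundary
  D2 <- outer((seq_len(256) - ph$occlusion$center[1])^2,
              (seq_len(256) - ph$occlusion$center[2])^2, "+")
  core_int <- D2 <= (ph$occlusion$radius_px - 6)^2 & nm$valid
  out_int <- D2 >= (ph$occlusion$radius_px + 6)^2 & nm$valid
  expect_equal(mean(nm$N[core_int]), 0.3, tolerance = 0.1)
  expect_equal(mean(nm$N[out_int]), 1.0, tolerance = 0.1)
  # flow ratio inside/outside matches the planted relative flow
  ratio <- mean(f1$cbf[core_int]) / mean(f1$cbf[out_int])
  expect_equal(ratio, 0.3, tolerance = 0.1)
})
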