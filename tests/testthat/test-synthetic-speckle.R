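# Scenario phantoms, the dynamic-speckle renderer, and motion injection.

test_that("baseline phantom has unit flow and no reduced pixels", {
  cfg <- scenario_config(image_shape = c(64L, 64L), target_area_15min = 3)
  ph <- flow_phantom(cfg, 0)
  expect_true(all(ph$relative_flow_map == 1))
  expect_identical(sum(ph$relative_flow_map < 0.5), 0L)
  expect_true(all(ph$tau_map > 0))
})

test_that("planted reduction area matches the growth curve on the grid", {
  # pitch 0.011 mm: planted pixel count = round(area / pitch^2)
  cfg <- scenario_config(image_shape = c(256L, 256L), pixel_pitch = 0.011,
                         target_area_15min = 0.35)
  ph <- flow_phantom(cfg, 15)
  n_target <- round(0.35 / 0.011^2)
  ring <- ceiling(2 * pi * ph$occlusion$radius_px)  # one perimeter ring
  expect_lte(abs(ph$occlusion$planted_pixels - n_target), ring)
  # flow inversely proportional to tau, pixelwise
  expect_equal(ph$relative_flow_map, cfg$baseline_tau / ph$tau_map,
               tolerance = 1e-12)
  # interior of the disc is below the reduction threshold
  expect_true(all(ph$relative_flow_map[ph$relative_flow_map < 1] < 0.5))
})

test_that("scaled 19.5 mm^2 territory is realized within one pixel ring", {
  cfg <- scenario_config(image_shape = c(256L, 256L),
                         target_area_15min = 19.5)
  ph <- flow_phantom(cfg, 15)
  expect_equal(ph$occlusion$planted_area_mm2, 19.5,
               tolerance = 2 * pi * ph$occlusion$radius_px *
                 cfg$pixel_pitch^2 / 19.5)
  # intermediate times follow the linear growth curve
  ph8 <- flow_phantom(cfg, 8)
  expect_equal(ph8$occlusion$planted_area_mm2, 19.5 * 8 / 15,
               tolerance = 0.05)
})

test_that("overscaled territories raise scenario-overflow", {
  expect_error(scenario_config(image_shape = c(64L, 64L),
                               pixel_pitch = 0.03,
                               target_area_15min = 10),
               "scenario-overflow")
  cfg <- scenario_config(image_shape = c(64L, 64L), pixel_pitch = 0.03,
                         target_area_15min = 1)
  cfg$growth_curve <- function(t) 10   # bypass constructor check
  expect_error(flow_phantom(cfg, 15), "scenario-overflow")
})

test_that("renderer reproduces the contrast model on uniform fields", {
  for (x in c(0.1, 1)) {
    cfg <- scenario_config(image_shape = c(128L, 128L),
                           baseline_tau = x * 0.005, n_substeps = 128L,
                           anatomy_amplitude = 0, target_area_15min = 0)
    fr <- render_speckle_frame(flow_phantom(cfg, 0), cfg, seed = 21)
    stk <- speckle_stack(fr, cfg$exposure, cfg$frame_rate, cfg$pixel_pitch)
    expect_equal(global_contrast(stk), sqrt(speckle_k2(x, 1)),
                 tolerance = 0.05)
  }
  # frozen speckle: K -> 1
  stk <- speckle_stack(frozen_frame, 5e-3, 50, 0.01)
  expect_equal(global_contrast(stk), 1, tolerance = 0.05)
})

test_that("beta scales the rendered squared contrast", {
  cfg <- scenario_config(image_shape = c(128L, 128L), beta = 0.5,
                         anatomy_amplitude = 0, target_area_15min = 0)
  fr <- render_speckle_frame(flow_phantom(cfg, 0), cfg, seed = 22)
  stk <- speckle_stack(fr, cfg$exposure, cfg$frame_rate, cfg$pixel_pitch)
  expect_equal(global_contrast(stk)^2,
               speckle_k2(cfg$baseline_tau, cfg$exposure, beta = 0.5),
               tolerance = 0.1)
})

test_that("renderer rejects undersampled integration", {
  cfg <- scenario_config(image_shape = c(64L, 64L), baseline_tau = 2e-4,
                         n_substeps = 64L, target_area_15min = 0)
  expect_error(render_speckle_frame(flow_phantom(cfg, 0), cfg, seed = 1),
               "undersampled-integration")
})

test_that("sequences sample at the frame rate and are seed-deterministic", {
  cfg <- scenario_config(image_shape = c(32L, 32L), target_area_15min = 0.2,
                         seed = 5)
  stk <- render_speckle_sequence(cfg, 0, 1 / 60)   # one second
  expect_identical(dim(stk$frames)[3], 50L)        # 50 fps
  expect_equal(stk$frame_rate, 50)
  expect_equal(stk$exposure, cfg$exposure)
  expect_equal(stk$pixel_pitch, cfg$pixel_pitch)
  stk2 <- render_speckle_sequence(cfg, 0, 1 / 60)
  expect_identical(stk$frames, stk2$frames)        # same config + seed
  expect_error(render_speckle_sequence(cfg, 1, 1), "empty-interval")
})

test_that("render_time_bins freezes the phantom per bin with ground truth", {
  cfg <- scenario_config(image_shape = c(48L, 48L), target_area_15min = 0.4,
                         frames_per_bin = 3L, seed = 6)
  bins <- render_time_bins(cfg, c(0, 8, 15))
  expect_length(bins, 3)
  expect_identical(dim(bins[[1]]$frames)[3], 3L)
  truth <- vapply(bins, function(b)
    attr(b, "phantom")$occlusion$planted_area_mm2, numeric(1))
  expect_identical(truth[[1]], 0)
  expect_true(all(diff(truth) > 0))
  bins2 <- render_time_bins(cfg, c(0, 8, 15))
  expect_identical(bins[[2]]$frames, bins2[[2]]$frames)
})

test_that("motion injection translates frames and round-trips", {
  stk <- speckle_stack(array(rep(frozen_frame, 3), c(dim(frozen_frame), 3)),
                       5e-3, 50, 0.01)
  zero <- matrix(0, 3, 2)
  expect_identical(inject_motion(stk, zero)$frames, stk$frames)
  # integer shift: content equals original indexed with the offset
  sch <- matrix(rep(c(3, -2), each = 3), 3, 2)
  j <- inject_motion(stk, sch)
  expect_equal(j$frames[10:60, 10:60, 1],
               stk$frames[10:60 + 2, 10:60 - 3, 1], tolerance = 1e-9)
  # subpixel round trip restores the stack almost exactly
  sch2 <- cbind(c(2.5, -1.25, 0.75), c(-3.5, 2.2, 0))
  back <- inject_motion(inject_motion(stk, sch2), -sch2)
  expect_lt(max(abs(back$frames - stk$frames)) / diff(range(stk$frames)),
            0.01)
  expect_error(inject_motion(stk, matrix(50, 3, 2)), "10%")
})
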