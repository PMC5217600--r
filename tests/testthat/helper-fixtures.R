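# Shared fixtures, built once per test run.  All synthetic; no files.

# Small static (frozen-speckle) frame: texture for registration tests and
# the static-contrast checks.
frozen_cfg <- scenario_config(image_shape = c(96L, 96L),
                              baseline_tau = 1e3, anatomy_amplitude = 0,
                              target_area_15min = 0, seed = 2)
frozen_frame <- render_speckle_frame(flow_phantom(frozen_cfg, 0),
                                     frozen_cfg, seed = 2)

# Uniform tau_c = T stack (x = 1), 12 frames at 128 px: used for the
# contrast-model spot checks and the estimator cross-validation.
x1_cfg <- scenario_config(image_shape = c(128L, 128L),
                          baseline_tau = 0.005,  # = exposure -> x = 1
                          anatomy_amplitude = 0,
                          target_area_15min = 0, seed = 3,
                          frames_per_bin = 12L)
x1_stack <- local({
  ph <- flow_phantom(x1_cfg, 0)
  frames <- speckleflow:::render_burst(ph, x1_cfg, 12L, seed = 3)
  speckle_stack(frames, x1_cfg$exposure, x1_cfg$frame_rate,
                x1_cfg$pixel_pitch)
})

# Global (whole-frame) contrast of a stack: ensemble estimator free of
# windowing loss, averaged over frames in K^2.
global_contrast <- function(stack) {
  nf <- dim(stack$frames)[3]
  k2 <- vapply(seq_len(nf), function(f) {
    img <- stack$frames[, , f]
    stats::var(as.vector(img)) / mean(img)^2
  }, numeric(1))
  sqrt(mean(k2))
}

# Build a norm_flow_map directly from an N matrix (for threshold tests).
nmap_of <- function(N, valid = !is.na(N), bin_time = NA_real_) {
  structure(list(N = N, valid = valid, bin_time = bin_time),
            class = "norm_flow_map")
}

# Build an area_series directly (for group-statistics tests).
series_of <- function(times, areas, kind = "CBF_50", pitch = 0.0273) {
  structure(list(times = times, areas = areas, kind = kind,
                 pixel_pitch = pitch),
            class = "area_series")
}

# Exact permutation p value for the two-sample Welch t statistic.
perm_p_welch <- function(a, b) {
  pool <- c(a, b); na <- length(a)
  t_obs <- ttest_groups(a, b)$t_stat
  idx <- utils::combn(length(pool), na)
  tperm <- apply(idx, 2, function(k) {
    x <- pool[k]; y <- pool[-k]
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  })
  mean(abs(tperm) >= abs(t_obs) - 1e-12)
}
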