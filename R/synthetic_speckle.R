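# Dynamic-speckle simulation with known correlation-time ground truth.
#
# Fields are band-limited circular complex Gaussian processes (fully
# developed speckle by construction); temporal decorrelation is an AR(1)
# evolution whose per-pixel coefficient exp(-dt / tau_c) realizes an
# exponential field autocorrelation, so the time-integrated intensity
# reproduces the single-exposure contrast model exactly in the limit of
# many sub-integration steps.

#' Configuration of a simulated occlusion scenario
#'
#' Bundles the acquisition geometry, speckle statistics and occlusion
#' time course for the simulator.  Defaults describe a focal arterial
#' occlusion forming over 15 minutes of illumination in a cranial-window
#' field of view, recorded at 50 fps.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_pitch mm per pixel.  The default maps a 7.0 mm window
#'   dimension onto the image width.
#' @param exposure camera exposure time T, seconds (must fit within the
#'   frame interval).
#' @param frame_rate frames per second.
#' @param beta instrumental coherence factor in (0, 1].
#' @param speckle_size speckle grain size in pixels (>= 2 keeps the grain
#'   Nyquist-sampled).
#' @param baseline_tau correlation time of healthy cortex, seconds.
#'   With the 5 ms default exposure this gives a baseline K around 0.4,
#'   typical of cortical LSCI.
#' @param occlusion_flow_fraction residual relative flow inside the
#'   occluded territory; the default 0.05 (a 95% reduction) models the
#'   near-zero flow of a complete photothrombotic occlusion.
#' @param target_area_15min true greater-than-50%-reduction area at
#'   t = 15 min, in mm^2.
#' @param growth_curve monotone function t (minutes) -> area (mm^2);
#'   default ramps linearly from 0 to `target_area_15min` over 15 min and
#'   plateaus thereafter.
#' @param occlusion_center c(row, col) of the occlusion disc in pixels;
#'   default is the centroid of the ipsilateral (left) hemisphere.
#' @param hemisphere `"left"` or `"right"` ipsilateral side.
#' @param n_substeps sub-integration steps per exposure (M); the renderer
#'   requires T / tau_c <= M / 4 everywhere.
#' @param frames_per_bin frames rendered per analysis time bin by the
#'   pipeline helpers.
#' @param anatomy_amplitude relative amplitude of the static reflectance
#'   (anatomy) field multiplying every frame.  Real cortical recordings
#'   carry persistent vessel/tissue structure; it is what frame-to-frame
#'   registration locks onto (pure dynamic speckle decorrelates completely
#'   between frames and is unregistrable).  Set to 0 for a uniform
#'   reflectance phantom when measuring pure speckle statistics.
#' @param anatomy_scale correlation length of the anatomy field, pixels.
#' @param seed integer RNG seed for all rendering (also fixes the anatomy
#'   pattern, which is constant across the whole scenario).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(image_shape = c(256L, 256L),
                            pixel_pitch = 7.0 / image_shape[2],
                            exposure = 0.005,
                            frame_rate = 50,
                            beta = 1.0,
                            speckle_size = 2,
                            baseline_tau = 1e-3,
                            occlusion_flow_fraction = 0.05,
                            target_area_15min = 19.5,
                            growth_curve = NULL,
                            occlusion_center = NULL,
                            hemisphere = "left",
                            n_substeps = 64L,
                            frames_per_bin = 12L,
                            anatomy_amplitude = 0.3,
                            anatomy_scale = 6,
                            seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            pixel_pitch > 0, exposure > 0, frame_rate > 0,
            beta > 0, beta <= 1, speckle_size >= 1, baseline_tau > 0,
            n_substeps >= 8, frames_per_bin >= 1,
            anatomy_amplitude >= 0, anatomy_amplitude < 1,
            anatomy_scale >= 2)
  if (occlusion_flow_fraction <= 0 || occlusion_flow_fraction >= 1)
    stop("occlusion_flow_fraction must lie in (0, 1)")
  if (exposure > 1 / frame_rate + 1e-12)
    stop("exposure cannot exceed the frame interval 1/frame_rate")
  hemi <- hemisphere_mask(image_shape, hemisphere)
  hemi_area <- sum(hemi) * pixel_pitch^2
  if (target_area_15min > hemi_area)
    stop("scenario-overflow: target area exceeds hemisphere area")
  if (is.null(growth_curve)) {
    target <- target_area_15min
    growth_curve <- function(t) target * pmin(pmax(t, 0) / 15, 1)
  }
  if (is.null(occlusion_center)) {
    half <- floor(image_shape[2] / 2)
    occlusion_center <- c(round(image_shape[1] / 2),
                          if (hemisphere == "left") round(half / 2)
                          else half + round((image_shape[2] - half) / 2))
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_pitch = pixel_pitch, exposure = exposure,
                 frame_rate = frame_rate, beta = beta,
                 speckle_size = speckle_size, baseline_tau = baseline_tau,
                 occlusion_flow_fraction = occlusion_flow_fraction,
                 target_area_15min = target_area_15min,
                 growth_curve = growth_curve,
                 occlusion_center = occlusion_center,
                 hemisphere = hemisphere,
                 n_substeps = as.integer(n_substeps),
                 frames_per_bin = as.integer(frames_per_bin),
                 anatomy_amplitude = anatomy_amplitude,
                 anatomy_scale = anatomy_scale,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario_config> %d x %d px @ %g mm/px, T = %g ms, %g fps\n",
           "  baseline tau_c = %g ms, core flow fraction = %g,\n",
           "  target >50%%-reduction area at 15 min = %g mm^2, seed = %d\n"),
    x$image_shape[1], x$image_shape[2], x$pixel_pitch, 1e3 * x$exposure,
    x$frame_rate, 1e3 * x$baseline_tau, x$occlusion_flow_fraction,
    x$target_area_15min, x$seed))
  invisible(x)
}

#' Flow phantom at a given scenario time
#'
#' Builds the ground-truth relative-flow and correlation-time maps for the
#' occlusion scenario at time `t` minutes after illumination onset.  The
#' reduced-flow territory is a disc (clipped by the hemisphere mask when
#' the requested area forces it against the midline) whose radius is
#' solved so the rasterized pixel count matches the growth-curve area to
#' within one perimeter-pixel ring.
#'
#' @param config a [scenario_config()].
#' @param t scenario time, minutes (>= 0; 0 = pre-stroke baseline).
#' @return a `flow_phantom`: `relative_flow_map`, `tau_map` (seconds,
#'   `baseline_tau / relative_flow`), `hemisphere_mask`,
#'   `occlusion` (center, radius_px, planted_pixels, planted_area_mm2),
#'   `pixel_pitch`, `scenario_time`.
#' @export
flow_phantom <- function(config, t) {
  stopifnot(inherits(config, "scenario_config"), t >= 0)
  dimi <- config$image_shape
  hemi <- hemisphere_mask(dimi, config$hemisphere)
  area <- config$growth_curve(t)
  n_target <- round(area / config$pixel_pitch^2)
  if (n_target > sum(hemi))
    stop("scenario-overflow: requested area exceeds hemisphere mask area")
  flow <- matrix(1, dimi[1], dimi[2])
  radius <- 0
  core <- matrix(FALSE, dimi[1], dimi[2])
  if (n_target > 0) {
    ctr <- config$occlusion_center
    D2 <- outer((seq_len(dimi[1]) - ctr[1])^2,
                (seq_len(dimi[2]) - ctr[2])^2, "+")
    count_at <- function(r) sum(D2 <= r^2 & hemi)
    lo <- 0; hi <- sqrt(max(D2)) + 1
    if (count_at(hi) < n_target)
      stop("scenario-overflow: requested area cannot be realized")
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (count_at(mid) < n_target) lo <- mid else hi <- mid
    }
    radius <- hi
    core <- D2 <= radius^2 & hemi
    flow[core] <- config$occlusion_flow_fraction
  }
  structure(list(relative_flow_map = flow,
                 tau_map = config$baseline_tau / flow,
                 hemisphere_mask = hemi,
                 occlusion = list(center = config$occlusion_center,
                                  radius_px = radius,
                                  planted_pixels = sum(core),
                                  planted_area_mm2 =
                                    sum(core) * config$pixel_pitch^2),
                 pixel_pitch = config$pixel_pitch,
                 scenario_time = t),
            class = "flow_phantom")
}

# Fourier support of the band-limited speckle field: indices of modes with
# |f| <= 1 / (2 * speckle_size) cycles/px.
speckle_fourier_mask <- function(dimi, speckle_size) {
  fr <- function(N) {
    k <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2)):-1)
    k / N
  }
  F2 <- outer(fr(dimi[1])^2, fr(dimi[2])^2, "+")
  which(F2 <= (1 / (2 * speckle_size))^2)
}

# One spatially correlated circular complex Gaussian field with unit
# mean intensity, synthesized directly on the Fourier support.
filtered_field <- function(mask_idx, dimi) {
  W <- matrix(0 + 0i, dimi[1], dimi[2])
  m <- length(mask_idx)
  W[mask_idx] <- complex(real = stats::rnorm(m),
                         imaginary = stats::rnorm(m)) / sqrt(2 * m)
  stats::fft(W, inverse = TRUE)
}

# Integrate |E|^2 over one exposure of M AR(1) sub-steps starting from
# field E0 (already stationary).  Returns the frame and the final field.
integrate_exposure <- function(E0, rho, amp, M, mask_idx, dimi) {
  E <- E0
  I <- Mod(E)^2
  for (s in seq_len(M - 1L)) {
    E <- rho * E + amp * filtered_field(mask_idx, dimi)
    I <- I + Mod(E)^2
  }
  list(frame = I / M, E = E)
}

check_integration <- function(config, tau_map) {
  if (config$exposure / min(tau_map) > config$n_substeps / 4)
    stop("undersampled-integration: T / tau_c exceeds n_substeps / 4; ",
         "increase n_substeps")
}

apply_beta <- function(frame, beta) {
  if (beta == 1) return(frame)
  pmax(1 + sqrt(beta) * (frame - 1), 0)
}

#' Static reflectance (anatomy) pattern of a scenario
#'
#' A smooth multiplicative field around 1 (low-pass-filtered Gaussian
#' noise with the configured correlation length), fixed by the scenario
#' seed and constant over time: the persistent tissue/vessel structure
#' that every frame shares and that registration locks onto.  Speckle
#' contrast (sd over mean) is locally invariant to it.
#'
#' @param config a [scenario_config()].
#' @return matrix of multiplicative reflectance factors (>= 0.05);
#'   identically 1 when `anatomy_amplitude` is 0.
#' @export
anatomy_field <- function(config) {
  dimi <- config$image_shape
  if (config$anatomy_amplitude == 0) return(matrix(1, dimi[1], dimi[2]))
  with_seed(config$seed + 7777L, {
    mask_idx <- speckle_fourier_mask(dimi, config$anatomy_scale)
    z <- Re(filtered_field(mask_idx, dimi))
    pmax(1 + config$anatomy_amplitude * z / stats::sd(z), 0.05)
  })
}

#' Render one time-integrated dynamic speckle frame
#'
#' Simulates a single camera exposure over the phantom's correlation-time
#' map: a stationary band-limited complex Gaussian field evolves through
#' `n_substeps` AR(1) steps with per-pixel coefficient
#' `exp(-dt / tau_c)`, and the intensity `|E|^2` is averaged over the
#' exposure.  The local contrast of an ensemble of such frames over a
#' uniform-tau region matches [speckle_k2()] to within a few percent
#' (discretization bias is O(dt / tau_c)).
#'
#' @param phantom a [flow_phantom()].
#' @param config the [scenario_config()].
#' @param seed RNG seed (NULL = continue current stream).
#' @return intensity matrix with unit mean (a.u.).
#' @export
render_speckle_frame <- function(phantom, config, seed = NULL) {
  stopifnot(inherits(phantom, "flow_phantom"))
  check_integration(config, phantom$tau_map)
  dimi <- config$image_shape
  A <- anatomy_field(config)
  with_seed(seed, {
    mask_idx <- speckle_fourier_mask(dimi, config$speckle_size)
    dt <- config$exposure / config$n_substeps
    rho <- exp(-dt / phantom$tau_map)
    amp <- sqrt(1 - rho^2)
    res <- integrate_exposure(filtered_field(mask_idx, dimi),
                              rho, amp, config$n_substeps, mask_idx, dimi)
    A * apply_beta(res$frame, config$beta)
  })
}

# Render n consecutive frames for a fixed phantom, carrying the field
# across inter-frame gaps with one exact AR(1) step.
render_burst <- function(phantom, config, n, seed = NULL) {
  check_integration(config, phantom$tau_map)
  dimi <- config$image_shape
  A <- anatomy_field(config)
  with_seed(seed, {
    mask_idx <- speckle_fourier_mask(dimi, config$speckle_size)
    dt <- config$exposure / config$n_substeps
    rho <- exp(-dt / phantom$tau_map)
    amp <- sqrt(1 - rho^2)
    gap <- 1 / config$frame_rate - config$exposure
    rho_g <- exp(-gap / phantom$tau_map)
    amp_g <- sqrt(1 - rho_g^2)
    frames <- array(0, c(dimi, n))
    E <- filtered_field(mask_idx, dimi)
    for (f in seq_len(n)) {
      res <- integrate_exposure(E, rho, amp, config$n_substeps,
                                mask_idx, dimi)
      frames[, , f] <- A * apply_beta(res$frame, config$beta)
      E <- rho_g * res$E + amp_g * filtered_field(mask_idx, dimi)
    }
    frames
  })
}

#' Render a continuously recorded speckle sequence
#'
#' Frames are sampled at the configured frame rate between `t_start` and
#' `t_end` (minutes); the occlusion phantom is updated along the growth
#' curve as the territory expands.  The field is carried across
#' inter-frame gaps with an exact AR(1) decorrelation step, so static
#' (large tau) speckle stays frozen across frames and fast speckle
#' decorrelates fully.
#'
#' @param config a [scenario_config()].
#' @param t_start,t_end interval in minutes since illumination onset
#'   (`t_start < t_end`).
#' @return a [speckle_stack()]; attribute `phantom_truth` records the
#'   planted reduction area (mm^2) at each frame time.
#' @export
render_speckle_sequence <- function(config, t_start, t_end) {
  stopifnot(inherits(config, "scenario_config"), t_start >= 0)
  if (t_start >= t_end) stop("empty-interval: t_start must precede t_end")
  fps <- config$frame_rate
  n <- round((t_end - t_start) * 60 * fps)
  if (n < 1) stop("empty-interval: no frame fits in the requested window")
  dimi <- config$image_shape
  frames <- array(0, c(dimi, n))
  truth <- numeric(n)
  A <- anatomy_field(config)
  with_seed(config$seed, {
    mask_idx <- speckle_fourier_mask(dimi, config$speckle_size)
    dt <- config$exposure / config$n_substeps
    gap <- 1 / fps - config$exposure
    phantom <- NULL
    rho <- amp <- rho_g <- amp_g <- NULL
    E <- filtered_field(mask_idx, dimi)
    last_n_px <- -1L
    for (f in seq_len(n)) {
      tmin <- t_start + (f - 1) / (60 * fps)
      n_px <- round(config$growth_curve(tmin) / config$pixel_pitch^2)
      if (n_px != last_n_px) {
        phantom <- flow_phantom(config, tmin)
        check_integration(config, phantom$tau_map)
        rho <- exp(-dt / phantom$tau_map); amp <- sqrt(1 - rho^2)
        rho_g <- exp(-gap / phantom$tau_map); amp_g <- sqrt(1 - rho_g^2)
        last_n_px <- n_px
      }
      res <- integrate_exposure(E, rho, amp, config$n_substeps,
                                mask_idx, dimi)
      frames[, , f] <- A * apply_beta(res$frame, config$beta)
      truth[f] <- phantom$occlusion$planted_area_mm2
      E <- rho_g * res$E + amp_g * filtered_field(mask_idx, dimi)
    }
  })
  stk <- speckle_stack(frames, config$exposure, fps, config$pixel_pitch,
                       timestamps = t_start * 60 + (seq_len(n) - 1) / fps)
  attr(stk, "phantom_truth") <- truth
  stk
}

#' Render per-minute analysis bins of a scenario
#'
#' The per-minute analysis bins of a long recording are represented by
#' short bursts of `frames_per_bin` consecutive frames with the phantom
#' frozen at each bin time; contrast statistics converge with tens of
#' frames, so full-rate rendering between bins adds nothing.
#'
#' @param config a [scenario_config()].
#' @param times bin times, minutes (0 = baseline, pre-stroke).
#' @return named list of [speckle_stack()]s, one per bin; each carries a
#'   `phantom` attribute with its ground truth.
#' @export
render_time_bins <- function(config, times) {
  stopifnot(inherits(config, "scenario_config"))
  out <- vector("list", length(times))
  names(out) <- sprintf("t%g", times)
  for (i in seq_along(times)) {
    phantom <- flow_phantom(config, times[i])
    frames <- render_burst(phantom, config, config$frames_per_bin,
                           seed = config$seed + 1000L * i)
    stk <- speckle_stack(frames, config$exposure, config$frame_rate,
                         config$pixel_pitch,
                         timestamps = times[i] * 60 +
                           (seq_len(config$frames_per_bin) - 1) /
                           config$frame_rate)
    attr(stk, "phantom") <- phantom
    out[[i]] <- stk
  }
  attr(out, "times") <- times
  out
}

#' Inject translational motion into a frame stack
#'
#' Translates each frame by a scheduled subpixel shift (bilinear
#' interpolation), emulating animal motion for registration tests.  The
#' schedule is attached as ground truth.
#'
#' @param stack a [speckle_stack()].
#' @param schedule numeric matrix (n_frames x 2) of per-frame (dx, dy)
#'   shifts in pixels; must stay below 10% of the image size.
#' @return the jittered stack with attribute `motion_schedule`.
#' @export
inject_motion <- function(stack, schedule) {
  stopifnot(inherits(stack, "speckle_stack"),
            is.matrix(schedule), ncol(schedule) == 2,
            nrow(schedule) == n_frames(stack))
  d <- dim(stack$frames)
  if (any(abs(schedule[, 1]) >= 0.1 * d[2]) ||
      any(abs(schedule[, 2]) >= 0.1 * d[1]))
    stop("motion shifts must stay below 10% of the image size")
  out <- stack
  for (f in seq_len(d[3])) {
    dx <- schedule[f, 1]; dy <- schedule[f, 2]
    if (dx != 0 || dy != 0)
      out$frames[, , f] <- translate_image(stack$frames[, , f], dx, dy)
  }
  attr(out, "motion_schedule") <- schedule
  out
}
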