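# Speckle contrast estimation from raw frame stacks.

#' Construct a speckle frame stack
#'
#' @param frames 3-D numeric array (rows x cols x frames) of nonnegative
#'   intensities, or a single matrix.
#' @param exposure camera exposure time T, seconds.
#' @param frame_rate acquisition rate, Hz.
#' @param pixel_pitch pixel size, mm/px.
#' @param timestamps optional per-frame times in seconds; defaults to a
#'   uniform grid at `frame_rate`.
#' @return a `speckle_stack` object.
#' @export
speckle_stack <- function(frames, exposure, frame_rate, pixel_pitch,
                          timestamps = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, all(frames >= 0, na.rm = TRUE),
            exposure > 0, frame_rate > 0, pixel_pitch > 0)
  if (exposure > 1 / frame_rate + 1e-12)
    stop("exposure cannot exceed the frame interval")
  nf <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(nf) - 1L) / frame_rate
  structure(list(frames = frames, exposure = exposure,
                 frame_rate = frame_rate, pixel_pitch = pixel_pitch,
                 timestamps = timestamps),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<speckle_stack> %d x %d px, %d frames @ %g fps, T = %g ms, pitch = %g mm\n",
    d[1], d[2], d[3], x$frame_rate, 1e3 * x$exposure, x$pixel_pitch))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

new_contrast_map <- function(K, valid, window, n_frames, bin_time,
                             exposure, pixel_pitch) {
  K[!valid] <- NA_real_
  structure(list(K = K, valid = valid, window = window,
                 n_frames_averaged = n_frames, bin_time = bin_time,
                 exposure = exposure, pixel_pitch = pixel_pitch),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf(
    "<contrast_map> %d x %d px, window %d, %d frame(s), %.1f%% valid\n",
    nrow(x$K), ncol(x$K), x$window, x$n_frames_averaged,
    100 * mean(x$valid)))
  invisible(x)
}

#' Spatial speckle contrast
#'
#' Per frame, computes the local contrast `K = sd / mean` over an odd
#' square window centred at each pixel (sample sd, n-1 denominator), then
#' averages the per-frame maps over the selected frames.  This is the
#' standard spatial estimator of single-exposure speckle contrast.
#' Multi-frame averaging is done on `K^2` (the physically additive
#' quantity, and the one the flow model is written in) and the square
#' root taken afterwards; averaging in `K` would add a flow-dependent
#' Jensen bias that no single coherence factor could absorb.
#'
#' Finite windows on finite-size speckle underestimate the ensemble
#' contrast by a constant factor (neighbouring pixels are correlated);
#' the factor is absorbed into the coherence factor beta, which
#' [estimate_beta()] measures from a static acquisition with the same
#' optics and window.
#'
#' Pixels whose window mean is not strictly positive are flagged invalid,
#' as is the border of width `(window - 1) / 2` where the window does not
#' fit.  An all-zero frame yields an all-invalid map with a warning.
#'
#' @param stack a [speckle_stack()].
#' @param window odd window width in pixels (default 7, the usual LSCI
#'   compromise between spatial resolution and estimator variance).
#' @param frames integer indices of the frames to average (default all).
#' @param bin_time optional time label (minutes) carried into downstream
#'   maps.
#' @return a `contrast_map`: `K` (matrix), `valid`, `window`,
#'   `n_frames_averaged`, `bin_time`.
#' @export
spatial_contrast <- function(stack, window = 7L, frames = NULL,
                             bin_time = NA_real_) {
  stopifnot(inherits(stack, "speckle_stack"))
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  if (length(frames) == 0) stop("frame bin is empty")
  w2 <- window^2
  acc <- NULL
  for (f in frames) {
    img <- stack$frames[, , f]
    if (all(img == 0)) {
      warning("all-zero frame encountered; contrast undefined")
      k <- matrix(NA_real_, nrow(img), ncol(img))
    } else {
      mu <- box_sum(img, window) / w2
      ex2 <- box_sum(img * img, window) / w2
      v <- (ex2 - mu^2) * w2 / (w2 - 1)
      k <- pmax(v, 0) / mu^2   # K^2; averaged across frames before sqrt
      k[!is.na(mu) & mu <= 0] <- NA_real_
    }
    acc <- if (is.null(acc)) k else acc + k
  }
  K <- sqrt(acc / length(frames))
  valid <- !is.na(K)
  new_contrast_map(K, valid, window, length(frames), bin_time,
                   stack$exposure, stack$pixel_pitch)
}

#' Temporal speckle contrast
#'
#' Per-pixel contrast `sd / mean` across `n_frames` consecutive frames.
#' Used as an independent estimator to cross-validate the spatial one:
#' on stationary, spatially uniform speckle both converge to the same
#' ensemble contrast.
#'
#' @param stack a [speckle_stack()].
#' @param n_frames number of frames to use (>= 8), starting at `start`.
#' @param start first frame index (default 1).
#' @param bin_time optional time label (minutes).
#' @return a `contrast_map` (window recorded as 1; no spatial border).
#' @export
temporal_contrast <- function(stack, n_frames, start = 1L,
                              bin_time = NA_real_) {
  stopifnot(inherits(stack, "speckle_stack"))
  if (n_frames < 8) stop("temporal contrast needs n_frames >= 8")
  if (start + n_frames - 1L > dim(stack$frames)[3])
    stop("n_frames exceeds stack length")
  sub <- stack$frames[, , start:(start + n_frames - 1L), drop = FALSE]
  d <- dim(sub)
  m <- matrix(sub, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  v <- (rowSums(m * m) - d[3] * mu^2) / (d[3] - 1)
  K <- sqrt(pmax(v, 0)) / mu
  K[mu <= 0] <- NA_real_
  K <- matrix(K, d[1], d[2])
  new_contrast_map(K, !is.na(K), 1L, n_frames, bin_time,
                   stack$exposure, stack$pixel_pitch)
}

#' Estimate the coherence factor beta from a static acquisition
#'
#' On a static scatterer the theoretical squared contrast saturates at
#' beta, so the mean `K^2` plateau of a contrast map computed from a
#' static (motion-free, frozen-speckle) stack with the analysis window
#' measures the effective beta -- the instrumental decorrelation ceiling
#' *including* the finite-window sampling loss, which is what the flow
#' inversion must divide out.
#'
#' @param stack a [speckle_stack()] of a static target.
#' @param window the contrast window that will be used in analysis.
#' @return effective beta (scalar in (0, 1]).
#' @export
estimate_beta <- function(stack, window = 7L) {
  cm <- spatial_contrast(stack, window = window)
  mean(cm$K[cm$valid]^2)
}

#' Calibrate the effective beta for a simulated optical configuration
#'
#' Renders independent frozen-speckle (static phantom) patterns with the
#' scenario's speckle size and measures [estimate_beta()] on them with
#' the analysis window.  The patterns must be independent -- a single
#' static pattern estimates the contrast plateau with only as many
#' degrees of freedom as it has speckle grains -- so each calibration
#' frame redraws the field (physically: the static target is moved
#' between calibration shots).  Fixed internal seeds keep the
#' calibration deterministic for a given configuration.
#'
#' @param config a [scenario_config()]; only the optical fields (image
#'   shape, speckle size, exposure, frame rate) are used.
#' @param window analysis window, px.
#' @param n_frames independent static patterns to average (default 24).
#' @return effective beta.
#' @export
calibrate_beta <- function(config, window = 7L, n_frames = 24L) {
  static_cfg <- config
  static_cfg$baseline_tau <- 1e6 * config$exposure  # frozen
  static_cfg$beta <- 1.0
  static_cfg$n_substeps <- 8L  # exact for a static field at any M
  phantom <- flow_phantom(static_cfg, 0)
  dimi <- static_cfg$image_shape
  frames <- array(0, c(dimi, n_frames))
  for (f in seq_len(n_frames))
    frames[, , f] <- render_speckle_frame(phantom, static_cfg,
                                          seed = 424242L + f)
  stk <- speckle_stack(frames, config$exposure, config$frame_rate,
                       config$pixel_pitch)
  estimate_beta(flatfield_correct(stk), window = window)
}

#' Flat-field correction: remove static reflectance structure
#'
#' Divides every frame by the Gaussian-smoothed temporal mean of the
#' stack (normalized to unit mean).  Anatomical reflectance (vessels,
#' tissue) multiplies the dynamic speckle and, left in place, leaks into
#' windowed contrast wherever it varies within the window; dividing it
#' out makes the contrast maps reflect speckle statistics alone.  This
#' is the standard flat-field step of speckle flowmetry pipelines and
#' must precede [spatial_contrast()] whenever frames carry visible
#' anatomy.  Motion correction must come first (the flat field is only
#' meaningful on co-registered frames).
#'
#' @param stack a [speckle_stack()].
#' @param sigma Gaussian sd (px) used to smooth the temporal mean before
#'   division.  It trades residual anatomy (too large a sigma leaves the
#'   reflectance in place) against speckle noise in the flat estimate
#'   (too small a sigma divides the frames by their own speckle); the
#'   default sits just above the speckle grain.
#' @return the corrected `speckle_stack`; attribute `flat_field` holds
#'   the estimated reflectance image.
#' @export
flatfield_correct <- function(stack, sigma = 2) {
  stopifnot(inherits(stack, "speckle_stack"))
  nf <- n_frames(stack)
  mu <- apply(stack$frames, c(1, 2), mean)
  flat <- gaussian_lowpass(mu, sigma)
  flat <- flat / mean(flat)
  flat <- pmax(flat, 0.05)
  out <- stack
  for (f in seq_len(nf)) out$frames[, , f] <- stack$frames[, , f] / flat
  attr(out, "flat_field") <- flat
  out
}
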