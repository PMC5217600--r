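# Single-exposure speckle model: forward evaluation, inversion to
# correlation time, and conversion of contrast maps to relative-flow maps.

#' Theoretical squared speckle contrast for a single exposure
#'
#' Evaluates the single-exposure speckle imaging equation for a Lorentzian
#' (exponential field autocorrelation) spectrum,
#' \deqn{K_s^2 = \beta \{ x + \tfrac{x^2}{2} (e^{-2/x} - 1) \}, \quad
#'       x = \tau_c / T,}
#' where \eqn{T} is the camera exposure time, \eqn{\tau_c} the speckle
#' decorrelation time and \eqn{\beta \in (0, 1]} the instrumental
#' coherence factor (detector/speckle size ratio, polarization).
#' \eqn{K_s^2} rises monotonically from \eqn{\beta x} (fast flow,
#' \eqn{x \to 0}) to \eqn{\beta} (static scatterers, \eqn{x \to \infty}).
#'
#' An asymptotic series is used for \eqn{x > 10^3} where the direct
#' expression loses precision to cancellation.
#'
#' @param tau_c correlation time(s), seconds; strictly positive.
#' @param exposure exposure time T, seconds; strictly positive scalar.
#' @param beta coherence factor in (0, 1].
#' @return squared contrast, same shape as `tau_c`; `NA` passes through.
#' @seealso [invert_contrast()], [contrast_to_flow()]
#' @export
speckle_k2 <- function(tau_c, exposure, beta = 1) {
  check_exposure_beta(exposure, beta)
  if (any(tau_c <= 0, na.rm = TRUE)) stop("tau_c must be positive")
  x <- tau_c / exposure
  k2 <- x + 0.5 * x^2 * expm1(-2 / x)
  big <- !is.na(x) & x > 1e3
  if (any(big)) {
    xb <- x[big]
    k2[big] <- 1 - 2 / (3 * xb) + 1 / (3 * xb^2) - 2 / (15 * xb^3)
  }
  beta * k2
}

# d K^2 / d x at beta = 1 (used by the Newton inversion)
speckle_k2_dx <- function(x) {
  d <- 1 + x * expm1(-2 / x) + exp(-2 / x)
  big <- !is.na(x) & x > 1e3
  if (any(big)) {
    xb <- x[big]
    d[big] <- 2 / (3 * xb^2) - 2 / (3 * xb^3) + 2 / (5 * xb^4)
  }
  d
}

check_exposure_beta <- function(exposure, beta) {
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure <= 0)
    stop("exposure must be a positive scalar (seconds)")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  invisible(TRUE)
}

#' Invert measured speckle contrast to correlation time
#'
#' Solves \eqn{K^2 = \beta f(\tau_c / T)} for \eqn{\tau_c} by a
#' damped Newton iteration in \eqn{\log(\tau_c/T)}; the forward model is
#' strictly increasing in \eqn{\tau_c}, so the root is unique.  Convergence
#' is to relative tolerance 1e-9 (usually 4--6 iterations).
#'
#' Degenerate pixels are flagged rather than thrown: `K^2 >= beta`
#' (static/clipped) returns `Inf`, and `K <= 0` or non-finite input
#' returns `NA` (invalid).
#'
#' @param K measured contrast (not squared); vector or matrix.
#' @param exposure exposure time T, seconds.
#' @param beta coherence factor in (0, 1].
#' @return correlation times in seconds, same shape as `K`; `Inf` where
#'   clipped, `NA` where invalid.
#' @export
invert_contrast <- function(K, exposure, beta = 1) {
  check_exposure_beta(exposure, beta)
  k2 <- as.numeric(K)^2
  out <- rep(NA_real_, length(k2))
  clipped <- is.finite(k2) & k2 >= beta & as.numeric(K) > 0
  out[clipped] <- Inf
  ok <- is.finite(k2) & as.numeric(K) > 0 & k2 < beta
  if (any(ok)) {
    target <- k2[ok] / beta
    # initial guess from the two asymptotic branches
    x <- ifelse(target < 0.5, pmax(target, 1e-12),
                2 / (3 * pmax(1 - target, 1e-12)))
    u <- log(x)
    for (iter in 1:60) {
      x <- exp(u)
      f <- speckle_k2(x, 1, 1) - target
      dfdu <- x * speckle_k2_dx(x)
      step <- f / dfdu
      step <- pmax(pmin(step, 2), -2)  # damp far-field steps
      u <- u - step
      if (max(abs(step)) < 1e-12) break
    }
    out[ok] <- exp(u) * exposure
  }
  if (is.matrix(K)) out <- matrix(out, nrow(K), ncol(K))
  out
}

#' Convert a contrast map to a relative blood-flow map
#'
#' Inverts each valid pixel of a [contrast map][spatial_contrast] to a
#' correlation time and reports relative flow `cbf = 1 / tau_c`
#' (arbitrary units; flow is assumed inversely proportional to the
#' correlation time).  Clipped pixels (contrast at or above the static
#' ceiling `sqrt(beta)`) map to zero flow; invalid pixels propagate.
#'
#' Only ratios of these maps to a baseline map are physically meaningful
#' downstream; no absolute velocity calibration is attempted.
#'
#' @param cmap a `contrast_map` from [spatial_contrast()] or
#'   [temporal_contrast()].
#' @param exposure exposure time T, seconds; defaults to the value carried
#'   by the contrast map.
#' @param beta coherence factor in (0, 1].
#' @return a `flow_map`: list with `cbf` (matrix, a.u.), `valid`,
#'   `clipped` (logical matrices), `bin_time`, `pixel_pitch`, `exposure`,
#'   `beta`.
#' @export
contrast_to_flow <- function(cmap, exposure = cmap$exposure, beta = 1) {
  stopifnot(inherits(cmap, "contrast_map"))
  tau <- invert_contrast(cmap$K, exposure, beta)
  cbf <- 1 / tau          # Inf -> 0 (no resolvable motion), NA propagates
  cbf[is.infinite(tau)] <- 0
  valid <- cmap$valid & !is.na(cbf)
  cbf[!valid] <- NA_real_
  structure(
    list(cbf = cbf, valid = valid,
         clipped = is.infinite(tau) & cmap$valid,
         bin_time = cmap$bin_time, pixel_pitch = cmap$pixel_pitch,
         exposure = exposure, beta = beta),
    class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("<flow_map> %d x %d px, %.1f%% valid, bin t = %s min\n",
              nrow(x$cbf), ncol(x$cbf), 100 * mean(x$valid),
              format(x$bin_time)))
  invisible(x)
}
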