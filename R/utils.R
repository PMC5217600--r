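# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Sets the RNG to a reproducible state for the duration of `expr` and
#' restores the caller's RNG state afterwards, so library calls never
#' perturb user-level random streams.  A `NULL` seed leaves the RNG alone.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Sliding-window box sum of a matrix
#'
#' Sum over the odd `w` x `w` window centred at each pixel, computed with
#' cumulative sums (O(1) per pixel).  Pixels whose window does not fit
#' entirely inside the image are `NA`.
#'
#' @param m numeric matrix.
#' @param w odd window width in pixels.
#' @return matrix of the same shape; `NA` border of width `(w-1)/2`.
#' @keywords internal
box_sum <- function(m, w) {
  stopifnot(w %% 2 == 1, w >= 1)
  n <- nrow(m); p <- ncol(m); h <- (w - 1L) / 2L
  if (n < w || p < w) stop("image smaller than window")
  out <- matrix(NA_real_, n, p)
  cs <- rbind(0, apply(m, 2, cumsum))
  rows <- (h + 1L):(n - h)
  a <- cs[rows + h + 1L, , drop = FALSE] - cs[rows - h, , drop = FALSE]
  cs2 <- cbind(0, t(apply(a, 1, cumsum)))
  cols <- (h + 1L):(p - h)
  out[rows, cols] <- cs2[, cols + h + 1L, drop = FALSE] -
    cs2[, cols - h, drop = FALSE]
  out
}

#' Translate an image by a (possibly subpixel) shift
#'
#' Content moves by `dx` pixels along columns (x) and `dy` along rows (y):
#' `out[i, j] = img[i - dy, j - dx]`.  The shift is applied as a Fourier
#' phase ramp (sinc interpolation, circular boundary): for band-limited
#' images -- which speckle intensity rendered at >= 2 px grain size is by
#' construction -- this interpolation is exact, integer shifts reduce to
#' a circular roll, and translating back restores the input to machine
#' precision.  Nonnegativity is preserved up to a float clamp.
#'
#' @param img numeric matrix.
#' @param dx,dy shift in pixels (positive moves content right / down).
#' @return translated matrix of the same shape.
#' @export
translate_image <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img); p <- ncol(img)
  fy <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  fx <- c(0:(ceiling(p / 2) - 1), -(floor(p / 2)):-1) / p
  ramp <- exp(-2i * pi * outer(fy * dy, fx * dx, "+"))
  out <- Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (n * p)
  if (min(img) >= 0) out <- pmax(out, 0)
  out
}

#' Gaussian low-pass filter via the Fourier domain (circular boundary)
#' @param img numeric matrix.
#' @param sigma Gaussian sd in pixels.
#' @return filtered matrix.
#' @keywords internal
gaussian_lowpass <- function(img, sigma) {
  n <- nrow(img); p <- ncol(img)
  fy <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  fx <- c(0:(ceiling(p / 2) - 1), -(floor(p / 2)):-1) / p
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (n * p)
}

#' Default hemisphere mask: a left/right half split at the image midline
#'
#' @param dim integer c(rows, cols).
#' @param side `"left"` (columns up to floor(cols/2)) or `"right"`.
#' @return logical matrix.
#' @export
hemisphere_mask <- function(dim, side = c("left", "right")) {
  side <- match.arg(side)
  half <- floor(dim[2] / 2)
  cols <- if (side == "left") seq_len(half) else (half + 1L):dim[2]
  m <- matrix(FALSE, dim[1], dim[2])
  m[, cols] <- TRUE
  m
}
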