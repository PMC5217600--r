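# Threshold-planimetry lesion and infarct volumetry from slice stacks.

#' Smooth a slice with a 3 x 3 Gaussian kernel
#'
#' Convolution with a normalized 3 x 3 Gaussian (sigma = 1 px), mirrored
#' borders.  This is the standard pre-filter before relative-maximum
#' thresholding of lesion slices.
#'
#' @param slice numeric matrix (>= 3 x 3).
#' @return smoothed matrix, same shape.
#' @export
smooth_slice <- function(slice) {
  n <- nrow(slice); p <- ncol(slice)
  if (n < 3 || p < 3) stop("slice must be at least 3 x 3")
  g <- stats::dnorm(-1:1, sd = 1)
  k <- outer(g, g) / sum(g)^2
  pad <- slice[c(2, 1:n, n - 1), c(2, 1:p, p - 1)]  # mirror borders
  out <- matrix(0, n, p)
  for (a in 0:2) for (b in 0:2)
    out <- out + k[a + 1, b + 1] * pad[(1:n) + a, (1:p) + b]
  out
}

#' Threshold a slice at a fraction of its maximum intensity
#'
#' Selects pixels at or above `frac` times the per-slice maximum (75% by
#' default).  The rule is relative, so it is invariant to global intensity
#' scaling; it presumes the lesion is the bright class and the background
#' stays below `frac` of the lesion intensity.  A slice whose maximum is
#' not positive returns an empty mask.
#'
#' @param slice numeric matrix (normally smoothed first).
#' @param frac threshold fraction of the slice maximum.
#' @return logical matrix.
#' @export
threshold_relmax <- function(slice, frac = 0.75) {
  mx <- max(slice)
  if (mx <= 0) return(matrix(FALSE, nrow(slice), ncol(slice)))
  slice >= frac * mx
}

new_lesion_result <- function(per_slice_area, thickness, thresholds, masks) {
  structure(list(per_slice_area = per_slice_area,
                 total_volume = sum(per_slice_area) * thickness,
                 slice_thickness = thickness,
                 threshold_used = thresholds,
                 masks = masks),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> %d slices x %g mm, total volume %.2f mm^3\n",
              length(x$per_slice_area), x$slice_thickness, x$total_volume))
  invisible(x)
}

#' Lesion volume by per-slice threshold planimetry
#'
#' Each slice is smoothed ([smooth_slice()]), thresholded at 75% of its
#' own maximum intensity ([threshold_relmax()]), and the masked area
#' (pixel count x pitch^2) is accumulated; the total volume is the sum of
#' per-slice areas times the slice thickness.
#'
#' @param vol a [volume_image()].
#' @param frac threshold fraction of the per-slice maximum (default 0.75).
#' @return a `lesion_result`: `per_slice_area` (mm^2), `total_volume`
#'   (mm^3), `threshold_used` (a.u. per slice), `masks`.
#' @export
lesion_volume <- function(vol, frac = 0.75) {
  stopifnot(inherits(vol, "volume_image"))
  ns <- dim(vol$slices)[3]
  areas <- thr <- numeric(ns)
  masks <- array(FALSE, dim(vol$slices))
  for (k in seq_len(ns)) {
    sm <- smooth_slice(vol$slices[, , k])
    m <- threshold_relmax(sm, frac)
    masks[, , k] <- m
    areas[k] <- sum(m) * vol$pixel_pitch^2
    thr[k] <- frac * max(sm)
  }
  new_lesion_result(areas, vol$slice_thickness, thr, masks)
}

#' Infarct volume from a TTC-like slice stack
#'
#' Applies the same smoothing + 75%-of-maximum planimetry to the pallor
#' channel of TTC-stained sections (infarcted tissue stays pale, i.e. is
#' the bright class of the analysed channel); slice thickness defaults to
#' the 3 mm of standard brain matrices via the volume's own geometry.
#'
#' @param vol a [volume_image()] with modality `"TTC-like"`.
#' @param frac threshold fraction (default 0.75).
#' @return a `lesion_result`.
#' @export
infarct_volume <- function(vol, frac = 0.75) {
  stopifnot(inherits(vol, "volume_image"))
  if (vol$modality != "TTC-like")
    stop("infarct_volume expects a TTC-like volume")
  lesion_volume(vol, frac)
}
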