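# Baseline normalization and hypo-/hyperperfusion area statistics.

#' Normalize flow maps to a pre-stroke baseline
#'
#' Pixel-by-pixel relative flow `N(x,y,t) = cbf(x,y,t) / cbf(x,y,0)`,
#' with baseline pixels below 1% of the baseline median flagged invalid
#' (division guard).
#'
#' @param series a `flow_map` or list of `flow_map`s (post-stroke bins).
#' @param baseline the pre-stroke `flow_map`.
#' @return a `norm_flow_map` (or list thereof, matching `series`): `N`
#'   matrix (1 = baseline level), `valid` mask, `bin_time`.
#' @export
normalize_to_baseline <- function(series, baseline) {
  stopifnot(inherits(baseline, "flow_map"))
  guard <- baseline$valid &
    baseline$cbf > 0.01 * stats::median(baseline$cbf[baseline$valid])
  if (!any(guard, na.rm = TRUE))
    stop("baseline flow map has no valid pixels")
  one <- function(fm) {
    stopifnot(inherits(fm, "flow_map"),
              all(dim(fm$cbf) == dim(baseline$cbf)))
    valid <- fm$valid & guard
    N <- fm$cbf / baseline$cbf
    N[!valid] <- NA_real_
    structure(list(N = N, valid = valid, bin_time = fm$bin_time),
              class = "norm_flow_map")
  }
  if (inherits(series, "flow_map")) one(series) else lapply(series, one)
}

new_perfusion_mask <- function(B, kind, threshold) {
  structure(list(B = B, threshold_kind = kind, threshold = threshold),
            class = "perfusion_mask")
}

#' Hypoperfusion mask: pixels with over 50% flow reduction
#'
#' Selects ipsilateral pixels whose normalized flow is strictly below the
#' reduction threshold (`N < 0.5` by default: an *over* 50% reduction, so
#' exactly 50% is excluded).
#'
#' @param nmap a `norm_flow_map` from [normalize_to_baseline()].
#' @param hemisphere logical matrix selecting the ipsilateral hemisphere.
#' @param threshold reduction threshold on N (default 0.5).
#' @return a `perfusion_mask` with logical matrix `B`.
#' @export
reduction_mask <- function(nmap, hemisphere, threshold = 0.5) {
  stopifnot(inherits(nmap, "norm_flow_map"),
            all(dim(hemisphere) == dim(nmap$N)))
  B <- !is.na(nmap$N) & nmap$N < threshold & hemisphere & nmap$valid
  new_perfusion_mask(B, "reduction", threshold)
}

#' Hyperperfusion mask: pixels with flow enhanced above baseline
#'
#' Strictly `N > threshold`; the default 1.2 imposes a 20% margin above
#' baseline so estimator noise around N = 1 is not counted as enhancement.
#'
#' @inheritParams reduction_mask
#' @param threshold enhancement threshold on N (> 1).
#' @return a `perfusion_mask`.
#' @export
enhancement_mask <- function(nmap, hemisphere, threshold = 1.2) {
  stopifnot(inherits(nmap, "norm_flow_map"), threshold > 1,
            all(dim(hemisphere) == dim(nmap$N)))
  B <- !is.na(nmap$N) & nmap$N > threshold & hemisphere & nmap$valid
  new_perfusion_mask(B, "enhancement", threshold)
}

#' Area of a perfusion mask in mm^2
#'
#' Pixel count times pitch squared.
#'
#' @param mask a `perfusion_mask` (or plain logical matrix).
#' @param pixel_pitch pixel size, mm/px.
#' @return area in mm^2.
#' @export
mask_area <- function(mask, pixel_pitch) {
  stopifnot(pixel_pitch > 0)
  B <- if (inherits(mask, "perfusion_mask")) mask$B else mask
  sum(B) * pixel_pitch^2
}

#' Check occlusion success against a regional CBF criterion
#'
#' TRUE iff the mean normalized flow over the arterial ROI shows an over
#' `criterion` decrease from baseline, i.e. `mean(N[roi]) < 1 - criterion`
#' (strict; the default 0.85 demands an over-85% drop).
#'
#' @param nmap a `norm_flow_map`.
#' @param roi logical matrix marking the monitored arterial region.
#' @param criterion required fractional CBF decrease (default 0.85).
#' @return logical scalar.
#' @export
occlusion_success <- function(nmap, roi, criterion = 0.85) {
  stopifnot(inherits(nmap, "norm_flow_map"),
            all(dim(roi) == dim(nmap$N)))
  sel <- roi & nmap$valid
  if (!any(sel)) stop("ROI contains no valid pixels")
  # formulated as the decrease itself so the strict boundary
  # (decrease exactly equal to the criterion) is float-exact
  (1 - mean(nmap$N[sel])) > criterion
}

new_area_series <- function(times, areas, kind, pixel_pitch) {
  structure(list(times = times, areas = areas, kind = kind,
                 pixel_pitch = pixel_pitch),
            class = "area_series")
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("<area_series> %s, %d bins\n", x$kind, length(x$times)))
  print(data.frame(time_min = x$times, area_mm2 = x$areas), row.names = FALSE)
  invisible(x)
}

#' @export
plot.area_series <- function(x, ...) {
  plot(x$times, x$areas, type = "b", xlab = "time (min)",
       ylab = expression(area ~ (mm^2)),
       main = if (x$kind == "CBF_50") "Hypoperfused area" else
         "Hyperperfused area", ...)
  invisible(x)
}

#' Hypo- and hyperperfusion area time series
#'
#' For each post-stroke time bin, normalizes the flow map to the baseline
#' and accumulates the over-50%-reduction area (CBF_50) and the enhanced
#' area (CBF_+) in mm^2.  The 15-minute bin, when present, is flagged as
#' the primary endpoint.
#'
#' @param flow_bins list of `flow_map`s, one per time bin, in time order.
#' @param baseline pre-stroke `flow_map`.
#' @param hemisphere ipsilateral hemisphere mask.
#' @param times bin times in minutes (same length as `flow_bins`).
#' @param pixel_pitch mm/px.
#' @param reduction_threshold threshold on N for CBF_50 (default 0.5).
#' @param enhancement_threshold threshold on N for CBF_+ (default 1.2).
#' @return list with `cbf50` and `cbfplus` [area series][print.area_series];
#'   attribute `endpoint` gives the index of the 15-min bin (NA if absent).
#' @export
area_time_series <- function(flow_bins, baseline, hemisphere, times,
                             pixel_pitch,
                             reduction_threshold = 0.5,
                             enhancement_threshold = 1.2) {
  stopifnot(length(flow_bins) == length(times), length(times) >= 1)
  if (is.unsorted(times)) stop("time bins must be ordered")
  nmaps <- normalize_to_baseline(flow_bins, baseline)
  a50 <- aplus <- numeric(length(times))
  for (i in seq_along(nmaps)) {
    a50[i] <- mask_area(
      reduction_mask(nmaps[[i]], hemisphere, reduction_threshold),
      pixel_pitch)
    aplus[i] <- mask_area(
      enhancement_mask(nmaps[[i]], hemisphere, enhancement_threshold),
      pixel_pitch)
  }
  out <- list(cbf50 = new_area_series(times, a50, "CBF_50", pixel_pitch),
              cbfplus = new_area_series(times, aplus, "CBF_plus",
                                        pixel_pitch))
  attr(out, "endpoint") <- if (any(times == 15)) which(times == 15)[1]
                           else NA_integer_
  out
}

#' Write an area-series pair as CSV
#'
#' @param series the list returned by [area_time_series()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_area_series <- function(series, path) {
  utils::write.csv(
    data.frame(time_min = series$cbf50$times,
               cbf50_mm2 = series$cbf50$areas,
               cbfplus_mm2 = series$cbfplus$areas),
    path, row.names = FALSE)
  invisible(path)
}
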