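# Slice-stack lesion phantoms and NSS score cohorts.

#' Construct a slice-stack volume image
#'
#' @param slices 3-D array (rows x cols x slices) of intensities, or a
#'   single matrix for a one-slice stack.
#' @param slice_thickness slice thickness, mm.
#' @param pixel_pitch in-plane pixel size, mm/px.
#' @param modality `"MRI-like"` (T2 hyperintense lesion) or `"TTC-like"`
#'   (pale infarct encoded as the bright channel).
#' @return a `volume_image` object.
#' @export
volume_image <- function(slices, slice_thickness, pixel_pitch,
                         modality = c("MRI-like", "TTC-like")) {
  modality <- match.arg(modality)
  if (is.matrix(slices)) slices <- array(slices, c(dim(slices), 1L))
  stopifnot(length(dim(slices)) == 3L, slice_thickness > 0, pixel_pitch > 0)
  structure(list(slices = slices, slice_thickness = slice_thickness,
                 pixel_pitch = pixel_pitch, modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf(
    "<volume_image> %s, %d x %d px x %d slices, %g mm thick, %g mm/px\n",
    x$modality, d[1], d[2], d[3], x$slice_thickness, x$pixel_pitch))
  invisible(x)
}

#' Generate a slice stack with a planted ellipsoidal lesion
#'
#' Plants a hyperintense ellipsoid of known volume in a noisy uniform
#' background.  The through-plane semi-axis always spans the full slice
#' stack, so every slice contains lesion tissue: the downstream per-slice
#' relative threshold is only defined on images that contain the bright
#' class (in practice the experimenter analyses lesion-containing slices).
#' The in-plane semi-axes are solved by bisection so the rasterized
#' voxel volume matches `true_volume` to within one voxel shell.
#'
#' @param true_volume planted lesion volume, mm^3 (0 = no lesion).
#' @param n_slices number of slices.
#' @param slice_thickness slice thickness, mm.
#' @param pixel_pitch in-plane pixel size, mm/px.
#' @param plane_shape c(rows, cols) of each slice.
#' @param lesion_intensity,background_intensity intensities (a.u.); the
#'   background must stay below 75% of the lesion so the relative
#'   threshold separates the classes.
#' @param noise_sd additive Gaussian noise sd (< 5% of lesion intensity).
#' @param modality passed to [volume_image()].
#' @param seed RNG seed.
#' @return a `volume_image` with attributes `truth_mask` (logical array)
#'   and `planted_volume_mm3` (rasterized ground truth).
#' @export
make_lesion_phantom <- function(true_volume, n_slices, slice_thickness,
                                pixel_pitch, plane_shape = c(64L, 64L),
                                lesion_intensity = 100,
                                background_intensity = 60,
                                noise_sd = 5,
                                modality = "MRI-like",
                                seed = NULL) {
  stopifnot(true_volume >= 0, n_slices >= 1, slice_thickness > 0,
            pixel_pitch > 0)
  if (background_intensity >= 0.75 * lesion_intensity)
    stop("background must stay below 75% of the lesion intensity")
  if (noise_sd > 0.05 * lesion_intensity)
    stop("noise_sd must not exceed 5% of the lesion intensity")
  voxvol <- pixel_pitch^2 * slice_thickness
  stack_vol <- prod(plane_shape) * n_slices * voxvol
  if (true_volume > stack_vol)
    stop("true_volume exceeds the stack volume")
  truth <- array(FALSE, c(plane_shape, n_slices))
  if (true_volume > 0) {
    n_target <- round(true_volume / voxvol)
    c_half <- n_slices * slice_thickness / 2
    zc <- (seq_len(n_slices) - 0.5) * slice_thickness - c_half
    ctr <- (plane_shape + 1) / 2
    X2 <- outer(((seq_len(plane_shape[1]) - ctr[1]) * pixel_pitch)^2,
                ((seq_len(plane_shape[2]) - ctr[2]) * pixel_pitch)^2, "+")
    count_at <- function(a) {
      tot <- 0L
      for (k in seq_len(n_slices)) {
        rad2 <- a^2 * (1 - (zc[k] / c_half)^2)
        if (rad2 > 0) tot <- tot + sum(X2 <= rad2)
      }
      tot
    }
    a_max <- min(plane_shape) / 2 * pixel_pitch * 0.98
    if (count_at(a_max) < n_target)
      stop("true_volume too large for the in-plane field of view")
    lo <- 0; hi <- a_max
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (count_at(mid) < n_target) lo <- mid else hi <- mid
    }
    a <- hi
    for (k in seq_len(n_slices)) {
      rad2 <- a^2 * (1 - (zc[k] / c_half)^2)
      if (rad2 > 0) truth[, , k] <- X2 <= rad2
    }
  }
  slices <- with_seed(seed, {
    s <- array(background_intensity, dim(truth))
    s[truth] <- lesion_intensity
    if (noise_sd > 0)
      s <- s + array(stats::rnorm(length(s), sd = noise_sd), dim(s))
    s
  })
  vol <- volume_image(slices, slice_thickness, pixel_pitch, modality)
  attr(vol, "truth_mask") <- truth
  attr(vol, "planted_volume_mm3") <- sum(truth) * voxvol
  vol
}

nss_category_maxima <- c(motor = 6L, sensory = 2L, beam = 6L, reflex = 4L)

# Allocate an integer total score across the four NSS categories,
# proportionally to the category maxima, by largest remainder.
allocate_nss <- function(total) {
  caps <- nss_category_maxima
  total <- max(0L, min(18L, as.integer(round(total))))
  base <- pmin(floor(total * caps / 18), caps)
  rem <- total - sum(base)
  fr <- total * caps / 18 - floor(total * caps / 18)
  for (i in order(fr, decreasing = TRUE)) {
    if (rem == 0) break
    if (base[i] < caps[i]) { base[i] <- base[i] + 1L; rem <- rem - 1L }
  }
  while (rem > 0) {
    j <- which(base < caps)[1]
    base[j] <- base[j] + 1L; rem <- rem - 1L
  }
  as.integer(base)
}

#' Simulate a cohort of neurological severity scores
#'
#' Each rat draws a latent severity from `N(group_mean, group_sd)`
#' (clipped to the 0--18 scale); each examiner/trial observation adds
#' independent Gaussian examiner noise and is then rounded to the integer
#' scoring grid and decomposed into the four category scores (motor 0--6,
#' sensory 0--2, beam balance 0--6, reflex/abnormal movement 0--4) by
#' largest-remainder allocation, so category bounds and the 18-point total
#' are respected by construction.
#'
#' @param group_mean,group_sd latent severity distribution (0--18 scale).
#' @param n_rats number of animals.
#' @param n_examiners independent examiners per rat (default 3).
#' @param n_trials trials per examiner (default 3).
#' @param examiner_sd sd of examiner/trial noise in score points.
#' @param seed RNG seed.
#' @return data.frame with columns rat_id, examiner_id, trial_index,
#'   motor, sensory, beam, reflex.
#' @export
make_nss_cohort <- function(group_mean, group_sd, n_rats,
                            n_examiners = 3L, n_trials = 3L,
                            examiner_sd = 0.5, seed = NULL) {
  stopifnot(group_mean >= 0, group_mean <= 18, group_sd >= 0,
            n_rats >= 1, n_examiners >= 1, n_trials >= 1, examiner_sd >= 0)
  with_seed(seed, {
    latent <- pmin(pmax(stats::rnorm(n_rats, group_mean, group_sd), 0), 18)
    rows <- vector("list", n_rats * n_examiners * n_trials)
    i <- 0L
    for (r in seq_len(n_rats)) {
      for (e in seq_len(n_examiners)) {
        for (tr in seq_len(n_trials)) {
          obs <- latent[r] +
            if (examiner_sd > 0) stats::rnorm(1, 0, examiner_sd) else 0
          cat4 <- allocate_nss(obs)
          i <- i + 1L
          rows[[i]] <- data.frame(rat_id = r, examiner_id = e,
                                  trial_index = tr,
                                  motor = cat4[1], sensory = cat4[2],
                                  beam = cat4[3], reflex = cat4[4])
        }
      }
    }
    do.call(rbind, rows)
  })
}
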