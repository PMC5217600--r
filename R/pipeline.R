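# End-to-end orchestration: simulate a two-group experiment to disk, then
# analyze a dataset directory into a group report.  All randomness lives
# in the simulation; the analysis path is deterministic.

#' Configuration of a full simulated experiment
#'
#' Defaults describe a two-group (conscious vs anesthetized) photothrombotic
#' occlusion experiment: per-rat hypoperfusion areas, lesion and infarct
#' volumes and NSS scores are drawn from the group distributions, imaged,
#' and analysed back.  Group means/SEMs default to the conditions this
#' pipeline is designed around; SEMs are converted to per-animal sd via
#' `sd = sem * sqrt(n)`.
#'
#' @param groups named list of two group specs; each a list with `n_rats`,
#'   `cbf50_mean`, `cbf50_sem` (mm^2 at 15 min), `lesion_mean`,
#'   `lesion_sem` (mm^3, MRI), `infarct_mean`, `infarct_sem` (mm^3, TTC),
#'   `nss_mean`, `nss_sem` (0--18).
#' @param scenario a [scenario_config()] used as the per-rat template
#'   (per-rat target areas and seeds are filled in per draw).
#' @param bin_times analysis bin times in minutes; 0 is the pre-stroke
#'   baseline.  Recording stops at 25 min post occlusion.
#' @param analysis list of analysis parameters: `window` (contrast window,
#'   px), `beta`, `reduction_threshold`, `enhancement_threshold`,
#'   `occlusion_criterion`, `alpha`, `var_equal`, `align` (register frames
#'   before contrast), `roi_halfwidth` (px, occlusion-check ROI).
#' @param mri list: `n_slices`, `thickness` (mm), `pitch` (mm),
#'   `plane_shape`.
#' @param ttc list: same fields for the TTC stack.
#' @param seed master seed; all per-rat seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(groups = NULL, scenario = NULL,
                       bin_times = c(0, 1:25),
                       analysis = list(), mri = list(), ttc = list(),
                       seed = 1L) {
  if (is.null(groups)) {
    groups <- list(
      conscious = list(n_rats = 11L, cbf50_mean = 19.5, cbf50_sem = 1.4,
                       lesion_mean = 63.7, lesion_sem = 11.2,
                       infarct_mean = 47, infarct_sem = 15,
                       nss_mean = 5.9, nss_sem = 1.0),
      anesthetic = list(n_rats = 11L, cbf50_mean = 12.4, cbf50_sem = 1.5,
                        lesion_mean = 40.1, lesion_sem = 6.2,
                        infarct_mean = 32, infarct_sem = 12,
                        nss_mean = 4.6, nss_sem = 1.0))
  }
  for (g in groups)
    if (is.null(g$n_rats) || g$n_rats < 1)
      stop("each group needs n_rats >= 1")
  if (is.null(scenario)) scenario <- scenario_config()
  analysis <- utils::modifyList(
    list(window = 7L, beta = "auto", reduction_threshold = 0.5,
         enhancement_threshold = 1.2, occlusion_criterion = 0.85,
         alpha = 0.05, var_equal = FALSE, align = FALSE,
         roi_halfwidth = 5L),
    analysis)
  mri <- utils::modifyList(
    list(n_slices = 20L, thickness = 1, pitch = 0.1,
         plane_shape = c(64L, 64L)), mri)
  ttc <- utils::modifyList(
    list(n_slices = 7L, thickness = 3, pitch = 0.1,
         plane_shape = c(64L, 64L)), ttc)
  stopifnot(analysis$reduction_threshold > 0,
            analysis$reduction_threshold < 1,
            analysis$enhancement_threshold > 1,
            analysis$occlusion_criterion > 0,
            analysis$occlusion_criterion < 1,
            analysis$alpha > 0, analysis$alpha < 1)
  structure(list(groups = groups, scenario = scenario,
                 bin_times = bin_times, analysis = analysis,
                 mri = mri, ttc = ttc, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; the
#' `scenario` block holds [scenario_config()] fields.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen <- if (!is.null(y$scenario)) do.call(scenario_config, y$scenario)
          else NULL
  run_config(groups = y$groups, scenario = scen,
             bin_times = if (!is.null(y$bin_times))
               as.numeric(y$bin_times) else c(0, 1:25),
             analysis = if (is.null(y$analysis)) list() else y$analysis,
             mri = if (is.null(y$mri)) list() else y$mri,
             ttc = if (is.null(y$ttc)) list() else y$ttc,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

truncnorm1 <- function(mean, sd, lower, upper) {
  x <- stats::rnorm(1, mean, sd)
  min(max(x, lower), upper)
}

pct_safe <- function(a, b) {
  if (is.finite(a) && is.finite(b) && b > 0) percent_difference(a, b)
  else NA_real_
}

#' Simulate a complete two-group dataset to disk
#'
#' For every rat: draws its true 15-min hypoperfusion area, MRI lesion
#' volume, TTC infarct volume and NSS severity from the group
#' distributions; renders the speckle time bins; writes the stacks
#' (TIFF + JSON), the MRI volume (NIfTI), the TTC stack (TIFF), per-rat
#' ground truth (JSON), per-group NSS tables (CSV), and a dataset
#' manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must be writable).
#' @return `out_dir`, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  scen <- config$scenario
  hemi_area <- sum(hemisphere_mask(scen$image_shape, scen$hemisphere)) *
    scen$pixel_pitch^2
  manifest <- list(groups = list(), bin_times = config$bin_times,
                   scenario = list(image_shape = scen$image_shape,
                                   pixel_pitch = scen$pixel_pitch,
                                   exposure = scen$exposure,
                                   frame_rate = scen$frame_rate,
                                   hemisphere = scen$hemisphere,
                                   occlusion_center = scen$occlusion_center,
                                   frames_per_bin = scen$frames_per_bin,
                                   speckle_size = scen$speckle_size,
                                   anatomy_amplitude = scen$anatomy_amplitude,
                                   anatomy_scale = scen$anatomy_scale),
                   analysis = config$analysis, seed = config$seed)
  rat_counter <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    rats <- character(g$n_rats)
    truths <- vector("list", g$n_rats)
    for (i in seq_len(g$n_rats)) {
      rat_counter <- rat_counter + 1L
      rat_seed <- config$seed + 7919L * rat_counter
      draws <- with_seed(rat_seed, list(
        cbf50 = truncnorm1(g$cbf50_mean, g$cbf50_sem * sqrt(g$n_rats),
                           0.5, 0.9 * hemi_area),
        lesion = truncnorm1(g$lesion_mean, g$lesion_sem * sqrt(g$n_rats),
                            1, Inf),
        infarct = truncnorm1(g$infarct_mean, g$infarct_sem * sqrt(g$n_rats),
                             1, Inf)))
      rat_id <- sprintf("%s_%02d", gname, i)
      rats[i] <- rat_id
      rdir <- file.path(out_dir, "rats", rat_id)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      rat_scen <- scen
      rat_scen$target_area_15min <- draws$cbf50
      rat_scen$growth_curve <- local({
        tgt <- draws$cbf50
        function(t) tgt * pmin(pmax(t, 0) / 15, 1)
      })
      rat_scen$seed <- rat_seed
      bins <- render_time_bins(rat_scen, config$bin_times)
      for (j in seq_along(bins))
        write_speckle_stack(bins[[j]],
                            file.path(rdir, sprintf("bin_%03d", j)))
      mri <- make_lesion_phantom(draws$lesion, config$mri$n_slices,
                                 config$mri$thickness, config$mri$pitch,
                                 config$mri$plane_shape,
                                 modality = "MRI-like",
                                 seed = rat_seed + 1L)
      write_volume_nifti(mri, file.path(rdir, "mri"))
      ttc <- make_lesion_phantom(draws$infarct, config$ttc$n_slices,
                                 config$ttc$thickness, config$ttc$pitch,
                                 config$ttc$plane_shape,
                                 modality = "TTC-like",
                                 seed = rat_seed + 2L)
      write_volume_tiff(ttc, file.path(rdir, "ttc"))
      truth <- list(cbf50_target_mm2 = draws$cbf50,
                    lesion_mm3 = attr(mri, "planted_volume_mm3"),
                    infarct_mm3 = attr(ttc, "planted_volume_mm3"),
                    seed = rat_seed)
      truths[[i]] <- truth
      jsonlite::write_json(truth, file.path(rdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    nss <- make_nss_cohort(g$nss_mean, g$nss_sem * sqrt(g$n_rats),
                           g$n_rats, seed = config$seed + 104729L +
                             match(gname, names(config$groups)))
    write_nss(nss, file.path(out_dir, sprintf("nss_%s.csv", gname)))
    manifest$groups[[gname]] <- list(n_rats = g$n_rats, rats = rats)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Resolve the analysis beta: "auto" calibrates the effective coherence
# factor (including the finite-window sampling loss) from a simulated
# static acquisition with the dataset's optics; deterministic.
resolve_beta <- function(an, scen) {
  if (identical(an$beta, "auto")) {
    cfg <- scenario_config(
      image_shape = as.integer(scen$image_shape),
      pixel_pitch = scen$pixel_pitch, exposure = scen$exposure,
      frame_rate = scen$frame_rate,
      speckle_size = if (!is.null(scen$speckle_size)) scen$speckle_size
                     else 2,
      anatomy_amplitude = if (!is.null(scen$anatomy_amplitude))
        scen$anatomy_amplitude else 0.3,
      anatomy_scale = if (!is.null(scen$anatomy_scale))
        scen$anatomy_scale else 6,
      target_area_15min = 0)
    calibrate_beta(cfg, window = an$window)
  } else as.numeric(an$beta)
}

# Analyse one rat's bin stacks into flow maps and area series.
analyze_rat_bins <- function(rdir, manifest, beta) {
  an <- manifest$analysis
  times <- as.numeric(manifest$bin_times)
  shape <- as.integer(manifest$scenario$image_shape)
  hemi <- hemisphere_mask(shape, manifest$scenario$hemisphere)
  flows <- vector("list", length(times))
  for (j in seq_along(times)) {
    stk <- read_speckle_stack(file.path(rdir, sprintf("bin_%03d", j)))
    if (isTRUE(an$align)) stk <- align_stack(stk)
    stk <- flatfield_correct(stk)
    cm <- spatial_contrast(stk, window = an$window, bin_time = times[j])
    flows[[j]] <- contrast_to_flow(cm, beta = beta)
  }
  base_idx <- which(times == 0)[1]
  if (is.na(base_idx)) stop("dataset has no baseline (t = 0) bin")
  baseline <- flows[[base_idx]]
  post <- flows[-base_idx]
  post_times <- times[-base_idx]
  series <- area_time_series(post, baseline, hemi, post_times,
                             manifest$scenario$pixel_pitch,
                             an$reduction_threshold,
                             an$enhancement_threshold)
  # occlusion check at the last bin, ROI centred on the illumination focus
  ctr <- as.integer(manifest$scenario$occlusion_center)
  hw <- as.integer(an$roi_halfwidth)
  roi <- matrix(FALSE, shape[1], shape[2])
  roi[max(1, ctr[1] - hw):min(shape[1], ctr[1] + hw),
      max(1, ctr[2] - hw):min(shape[2], ctr[2] + hw)] <- TRUE
  nlast <- normalize_to_baseline(post[[length(post)]], baseline)
  occluded <- occlusion_success(nlast, roi, an$occlusion_criterion)
  list(series = series, occluded = occluded, times = post_times)
}

#' Analyse a simulated (or equivalently structured) dataset directory
#'
#' Runs the full analysis chain on every rat: contrast, optional
#' registration, flow inversion, baseline normalization, CBF_50 / CBF_+
#' area series, occlusion-success check (animals failing it are excluded
#' with a logged reason), MRI lesion volumetry, TTC infarct volumetry and
#' NSS totals; then compares the two groups (Welch or pooled t tests,
#' mean +/- SEM, per-timepoint series comparison, percent differences).
#'
#' The analysis path contains no randomness: re-running on the same
#' dataset reproduces the report bit for bit.
#'
#' @param config a [run_config()] (its `analysis` block can override the
#'   manifest's); pass `NULL` to use the dataset manifest as-is.
#' @param dataset_dir directory written by [run_simulation()].
#' @return the report (list); also written as `report.json` and a human
#'   log under `dataset_dir`.
#' @export
run_analysis <- function(config, dataset_dir) {
  mpath <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(mpath)) stop("not a dataset directory: ", dataset_dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!is.null(config)) {
    stopifnot(inherits(config, "run_config"))
    manifest$analysis <- utils::modifyList(manifest$analysis,
                                           config$analysis)
  }
  an <- manifest$analysis
  beta <- resolve_beta(an, manifest$scenario)
  groups <- list()
  excluded <- character()
  for (gname in names(manifest$groups)) {
    rats <- manifest$groups[[gname]]$rats
    nss_tab <- read_nss(file.path(dataset_dir,
                                  sprintf("nss_%s.csv", gname)))
    cbf50_15 <- lesion <- infarct <- nss <- numeric(0)
    series_list <- list()
    for (i in seq_along(rats)) {
      rdir <- file.path(dataset_dir, "rats", rats[i])
      res <- analyze_rat_bins(rdir, manifest, beta)
      if (!res$occluded) {
        excluded <- c(excluded, sprintf(
          "%s: occlusion criterion (>%g%% decrease) not met", rats[i],
          100 * an$occlusion_criterion))
        next
      }
      ep <- attr(res$series, "endpoint")
      if (is.na(ep)) ep <- length(res$times)
      cbf50_15 <- c(cbf50_15, res$series$cbf50$areas[ep])
      series_list[[length(series_list) + 1L]] <- res$series$cbf50
      mri <- read_volume_nifti(file.path(rdir, "mri"))
      lesion <- c(lesion, lesion_volume(mri)$total_volume)
      ttc <- read_volume_tiff(file.path(rdir, "ttc"))
      infarct <- c(infarct, infarct_volume(ttc)$total_volume)
      nss <- c(nss, nss_total(nss_tab[nss_tab$rat_id == i, ]))
    }
    groups[[gname]] <- list(n_analyzed = length(cbf50_15),
                            cbf50_15min_mm2 = cbf50_15,
                            lesion_mm3 = lesion, infarct_mm3 = infarct,
                            nss = nss, series = series_list)
  }
  ga <- groups[[1]]; gb <- groups[[2]]
  # group tests need n >= 2 per arm; smaller (post-exclusion) groups are
  # reported descriptively with NA statistics rather than failing
  cmp <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) {
      return(list(mean_a = mean(a), sem_a = NA_real_, mean_b = mean(b),
                  sem_b = NA_real_, t = NA_real_, p = NA_real_,
                  significant = NA))
    }
    x <- ttest_groups(a, b, var_equal = isTRUE(an$var_equal),
                      alpha = an$alpha)
    list(mean_a = x$mean_a, sem_a = x$sem_a, mean_b = x$mean_b,
         sem_b = x$sem_b, t = x$t_stat, p = x$p_value,
         significant = x$significant)
  }
  tp <- if (length(ga$series) >= 2 && length(gb$series) >= 2) {
    timepoint_comparison(ga$series, gb$series,
                         var_equal = isTRUE(an$var_equal),
                         alpha = an$alpha)
  } else {
    data.frame()
  }
  report <- list(
    groups = stats::setNames(
      lapply(groups, function(g) g[setdiff(names(g), "series")]),
      names(groups)),
    comparisons = list(
      cbf50_15min = cmp(ga$cbf50_15min_mm2, gb$cbf50_15min_mm2),
      lesion = cmp(ga$lesion_mm3, gb$lesion_mm3),
      infarct = cmp(ga$infarct_mm3, gb$infarct_mm3),
      nss = cmp(ga$nss, gb$nss)),
    percent_differences = list(
      lesion_mri = pct_safe(mean(ga$lesion_mm3), mean(gb$lesion_mm3)),
      nss = pct_safe(mean(ga$nss), mean(gb$nss)),
      infarct_ttc = pct_safe(mean(ga$infarct_mm3),
                             mean(gb$infarct_mm3))),
    cbf50_timepoints = tp,
    excluded = excluded,
    parameters = c(an, list(beta_resolved = beta)))
  jsonlite::write_json(report, file.path(dataset_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(sprintf("speckleflow analysis of %s", dataset_dir),
           sprintf("groups: %s", paste(names(groups), collapse = " vs ")),
           sprintf("excluded: %s",
                   if (length(excluded)) paste(excluded, collapse = "; ")
                   else "none"),
           sprintf("CBF50 @15min: %.2f +/- %.2f vs %.2f +/- %.2f mm^2 (p=%.3g)",
                   report$comparisons$cbf50_15min$mean_a,
                   report$comparisons$cbf50_15min$sem_a,
                   report$comparisons$cbf50_15min$mean_b,
                   report$comparisons$cbf50_15min$sem_b,
                   report$comparisons$cbf50_15min$p),
           sprintf("percent differences (MRI/NSS/TTC): %.1f / %.1f / %.1f",
                   report$percent_differences$lesion_mri,
                   report$percent_differences$nss,
                   report$percent_differences$infarct_ttc))
  writeLines(log, file.path(dataset_dir, "analysis.log"))
  report
}
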