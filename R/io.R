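# Standard-format I/O: multi-page TIFF + JSON sidecars for frame stacks
# and maps, NIfTI for volumes, CSV for scores.

#' Write a speckle stack as multi-page 16-bit TIFF with JSON metadata
#'
#' Intensities are scaled by the stack maximum into the 16-bit range; the
#' scale and acquisition metadata (exposure, frame rate, pixel pitch,
#' timestamps) go into `<path>.json` next to `<path>.tif`.
#'
#' @param stack a [speckle_stack()].
#' @param path_base output path without extension.
#' @return `path_base`, invisibly.
#' @export
write_speckle_stack <- function(stack, path_base) {
  stopifnot(inherits(stack, "speckle_stack"))
  mx <- max(stack$frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(f) stack$frames[, , f] / mx)
  tiff::writeTIFF(pages, paste0(path_base, ".tif"), bits.per.sample = 16L)
  meta <- list(exposure_s = stack$exposure,
               frame_rate_hz = stack$frame_rate,
               pixel_pitch_mm = stack$pixel_pitch,
               intensity_scale = mx,
               timestamps_s = stack$timestamps)
  jsonlite::write_json(meta, paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_base)
}

#' Read a speckle stack written by [write_speckle_stack()]
#'
#' @param path_base path without extension.
#' @return a [speckle_stack()].
#' @export
read_speckle_stack <- function(path_base) {
  meta <- jsonlite::read_json(paste0(path_base, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_base, ".tif"), all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    frames[, , f] <- pages[[f]] * meta$intensity_scale
  speckle_stack(frames, meta$exposure_s, meta$frame_rate_hz,
                meta$pixel_pitch_mm, timestamps = meta$timestamps_s)
}

#' Write a volume image as NIfTI (+ JSON modality sidecar)
#'
#' Voxel dimensions (in-plane pitch, slice thickness) are stored in the
#' NIfTI header; the modality tag, which NIfTI cannot carry, goes into a
#' JSON sidecar.
#'
#' @param vol a [volume_image()].
#' @param path_base path without extension (writes `.nii.gz` + `.json`).
#' @return `path_base`, invisibly.
#' @export
write_volume_nifti <- function(vol, path_base) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$slices)
  RNifti::pixdim(img) <- c(vol$pixel_pitch, vol$pixel_pitch,
                           vol$slice_thickness)
  RNifti::writeNifti(img, paste0(path_base, ".nii.gz"))
  jsonlite::write_json(list(modality = vol$modality),
                       paste0(path_base, ".json"), auto_unbox = TRUE)
  invisible(path_base)
}

#' Read a volume image written by [write_volume_nifti()]
#'
#' @param path_base path without extension.
#' @return a [volume_image()].
#' @export
read_volume_nifti <- function(path_base) {
  img <- RNifti::readNifti(paste0(path_base, ".nii.gz"))
  pd <- RNifti::pixdim(img)
  side <- paste0(path_base, ".json")
  modality <- if (file.exists(side))
    jsonlite::read_json(side)$modality else "MRI-like"
  volume_image(array(as.numeric(img), dim(img)),
               slice_thickness = pd[3], pixel_pitch = pd[1],
               modality = modality)
}

#' Write a volume image as multi-page TIFF + JSON geometry
#'
#' Plain-text-adjacent alternative to NIfTI for TTC-like photographic
#' stacks: one page per slice, intensities scaled by the stack maximum.
#'
#' @param vol a [volume_image()].
#' @param path_base path without extension.
#' @return `path_base`, invisibly.
#' @export
write_volume_tiff <- function(vol, path_base) {
  stopifnot(inherits(vol, "volume_image"))
  mx <- max(vol$slices)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(vol$slices)[3]),
                  function(k) pmax(vol$slices[, , k], 0) / mx)
  tiff::writeTIFF(pages, paste0(path_base, ".tif"), bits.per.sample = 16L)
  jsonlite::write_json(list(slice_thickness_mm = vol$slice_thickness,
                            pixel_pitch_mm = vol$pixel_pitch,
                            modality = vol$modality,
                            intensity_scale = mx),
                       paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_base)
}

#' Read a volume image written by [write_volume_tiff()]
#'
#' @param path_base path without extension.
#' @return a [volume_image()].
#' @export
read_volume_tiff <- function(path_base) {
  meta <- jsonlite::read_json(paste0(path_base, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_base, ".tif"), all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  slices <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    slices[, , k] <- pages[[k]] * meta$intensity_scale
  volume_image(slices, meta$slice_thickness_mm, meta$pixel_pitch_mm,
               meta$modality)
}

#' Write / read an NSS cohort table as CSV
#'
#' @param records data.frame from [make_nss_cohort()].
#' @param path CSV path.
#' @return the path (write) or the records data.frame (read).
#' @export
write_nss <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nss
#' @export
read_nss <- function(path) {
  utils::read.csv(path)
}

#' Write a contrast or flow map as 32-bit float TIFF
#'
#' Values are stored scaled by the map maximum (recorded in the JSON
#' sidecar); invalid pixels are written as zero and recorded in the mask.
#'
#' @param map a `contrast_map` or `flow_map`.
#' @param path_base path without extension.
#' @return `path_base`, invisibly.
#' @export
write_map_tiff <- function(map, path_base) {
  vals <- if (inherits(map, "contrast_map")) map$K else map$cbf
  v <- vals
  v[is.na(v)] <- 0
  mx <- max(v)
  if (mx <= 0) mx <- 1
  tiff::writeTIFF(v / mx, paste0(path_base, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(intensity_scale = mx,
                            kind = class(map)[1]),
                       paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_base)
}
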