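#' Read and write pipeline data files
#'
#' All tabular artifacts use headed CSV with fixed column names:
#' turbidity curves (`time_min`, `absorbance`, `turbidity`), FTIR spectra
#' (`wavenumber_cm-1`, `absorbance`), reflectance profiles
#' (`wavelength_nm`, `distance_um`, `reflectance`) and inverted scattering
#' spectra (`wavelength_nm`, `mus_prime_mm-1`, `residual`,
#' `boundary_flag`). Image stacks are multi-page TIFF; intensities are
#' scaled to `[0, 1]` on write (the scale factor and the voxel sizes travel
#' in a JSON sidecar `<path>.meta.json`, since the TIFF writer carries no
#' free-form tags).
#'
#' @param x object to write.
#' @param path file path.
#' @name matrixage-io
NULL

#' @rdname matrixage-io
#' @export
write_curve_csv <- function(x, path) {
  write.csv(as.data.frame(x[, c("time_min", "absorbance", "turbidity")]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrixage-io
#' @export
read_curve_csv <- function(path) {
  as_turbidity_curve(read.csv(path))
}

#' @rdname matrixage-io
#' @export
write_spectrum_csv <- function(x, path) {
  df <- data.frame(`wavenumber_cm-1` = x$wavenumber, absorbance = x$absorbance,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrixage-io
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  out <- tibble(wavenumber = df[["wavenumber_cm-1"]], absorbance = df[["absorbance"]])
  class(out) <- c("ftir_spectrum", class(out))
  attr(out, "preprocessing") <- c(baseline_corrected = FALSE,
                                  offset_corrected = FALSE,
                                  vector_normalized = FALSE)
  out
}

#' @rdname matrixage-io
#' @param geometry optional [detector_geometry()] reattached on read.
#' @export
write_profile_csv <- function(x, path) {
  write.csv(as.data.frame(x[, c("wavelength_nm", "distance_um", "reflectance")]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrixage-io
#' @export
read_profile_csv <- function(path, geometry = NULL) {
  out <- as_tibble(read.csv(path))
  if (is.null(geometry)) {
    centers <- sort(unique(out$distance_um))
    geometry <- detector_geometry(centers)
  }
  attr(out, "geometry") <- geometry
  class(out) <- c("reflectance_profile", class(out))
  out
}

#' @rdname matrixage-io
#' @export
write_mus_prime_csv <- function(x, path) {
  df <- data.frame(wavelength_nm = x$wavelength_nm,
                   `mus_prime_mm-1` = x$mus_prime,
                   residual = x$residual,
                   boundary_flag = x$boundary_flag,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrixage-io
#' @export
write_stack_tiff <- function(x, path) {
  stopifnot(inherits(x, "image_stack"))
  mx <- max(x$voxels)
  scale <- if (mx > 0) mx else 1
  slices <- lapply(seq_len(dim(x$voxels)[3]), function(i) x$voxels[, , i] / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(pixel_size_xy_um = x$pixel_size_xy, z_step_um = x$z_step,
         intensity_scale = scale),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname matrixage-io
#' @param pixel_size_xy,z_step voxel-size overrides (um) when no sidecar
#'   metadata is present.
#' @export
read_stack_tiff <- function(path, pixel_size_xy = NULL, z_step = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  px <- pixel_size_xy %||% meta$pixel_size_xy_um %||%
    abort("no pixel size in sidecar metadata; supply pixel_size_xy")
  zs <- z_step %||% meta$z_step_um %||%
    abort("no z step in sidecar metadata; supply z_step")
  scale <- meta$intensity_scale %||% 1
  vol <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices))) * scale
  image_stack(vol, px, zs)
}
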