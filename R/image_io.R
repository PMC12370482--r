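# Readers/writers for the three interchange formats the pipeline touches:
# two-channel fluorescence TIFFs, calibrated thermal stacks (degrees C), and
# exposure logs (CSV). Each carries a JSON sidecar; readers validate rather
# than coerce.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

read_sidecar <- function(path, required) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) .ll_error(paste0("missing JSON sidecar: ", sp), "laserlesion_schema_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    .ll_error(paste0("sidecar missing required field(s): ", paste(missing, collapse = ", ")),
              "laserlesion_schema_error")
  meta
}

#' Two-channel live/dead fluorescence image
#'
#' Container for one calcein (live, green) / ethidium (dead, red) frame.
#'
#' @param green,red numeric matrices of identical dimensions, intensities in
#'   16-bit counts
#' @param pixel_pitch micrometres per pixel (> 0)
#' @param metadata free-form named list (beam geometry, seed, ...)
#' @return object of class `two_channel_image`
#' @export
two_channel_image <- function(green, red, pixel_pitch, metadata = list()) {
  if (!is.matrix(green) || !is.matrix(red) || !identical(dim(green), dim(red)))
    .ll_error("green and red channels must be matrices of identical dimensions",
              "laserlesion_validation_error")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 || pixel_pitch <= 0)
    .ll_error("pixel_pitch must be a single positive number", "laserlesion_validation_error")
  structure(list(green = green, red = red, pixel_pitch = pixel_pitch,
                 metadata = metadata),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, pitch %.3g um/px\n",
              nrow(x$green), ncol(x$green), x$pixel_pitch))
  invisible(x)
}

#' Calibrated thermal video
#'
#' @param frames 3-D array (frame, row, col) of temperatures in degrees C
#' @param fps frames per second (> 0)
#' @param pixel_pitch micrometres per pixel
#' @param ambient ambient temperature, degrees C
#' @param exposure_window integer `(start_frame, end_frame)`, 0-based half-open
#'   window of frames during which the laser was on
#' @return object of class `thermal_video`
#' @export
thermal_video <- function(frames, fps, pixel_pitch, ambient, exposure_window) {
  if (length(dim(frames)) != 3)
    .ll_error("frames must be a 3-D array (frame, row, col)", "laserlesion_validation_error")
  if (!is.numeric(fps) || fps <= 0) .ll_error("fps must be > 0", "laserlesion_validation_error")
  if (any(!is.finite(frames))) {
    bad <- which(apply(!is.finite(frames), 1, any))
    .ll_error(paste0("non-finite temperatures in frame(s): ",
                     paste(bad - 1L, collapse = ", ")), "laserlesion_validation_error")
  }
  ew <- as.integer(exposure_window)
  if (length(ew) != 2 || ew[1] < 0 || ew[2] > dim(frames)[1] || ew[1] >= ew[2])
    .ll_error("exposure_window must be a valid 0-based half-open frame range",
              "laserlesion_validation_error")
  structure(list(frames = frames, fps = fps, pixel_pitch = pixel_pitch,
                 ambient = ambient, exposure_window = ew),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_video> %d frames of %d x %d px @ %g fps, ambient %.1f C\n",
              d[1], d[2], d[3], x$fps, x$ambient))
  invisible(x)
}

#' Write / read a fluorescence image as 2-page 16-bit TIFF + JSON sidecar
#'
#' Page 1 is the green (live) channel, page 2 the red (dead) channel. The
#' sidecar holds `pixel_pitch_um` plus any extra metadata; round-trips are
#' lossless for integer 16-bit data.
#'
#' @param img a [two_channel_image()]
#' @param path output `.tif` path (sidecar written alongside as `.json`)
#' @export
write_fluorescence <- function(img, path) {
  stopifnot(inherits(img, "two_channel_image"))
  write_tiff_pages(list(round(img$green), round(img$red)), path, format = "uint16")
  meta <- c(list(pixel_pitch_um = img$pixel_pitch), img$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fluorescence
#' @return `read_fluorescence()` returns a [two_channel_image()]
#' @export
read_fluorescence <- function(path) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 2)
    .ll_error(sprintf("fluorescence TIFF must have exactly 2 pages, found %d", length(pages)),
              "laserlesion_format_error")
  meta <- read_sidecar(path, required = "pixel_pitch_um")
  two_channel_image(pages[[1]], pages[[2]], pixel_pitch = meta$pixel_pitch_um,
                    metadata = meta[setdiff(names(meta), "pixel_pitch_um")])
}

#' Write / read a thermal stack as multi-page float32 TIFF + JSON sidecar
#'
#' Temperatures are stored directly in degrees C (the instrument calibration
#' that produced them is out of scope). The sidecar requires `fps`,
#' `pixel_pitch_um`, `ambient_C`, `exposure_start_frame`, `exposure_end_frame`.
#'
#' @param video a [thermal_video()]
#' @param path output `.tif` path
#' @export
write_thermal <- function(video, path) {
  stopifnot(inherits(video, "thermal_video"))
  n <- dim(video$frames)[1]
  pages <- lapply(seq_len(n), function(i) video$frames[i, , ])
  write_tiff_pages(pages, path, format = "float32")
  meta <- list(fps = video$fps, pixel_pitch_um = video$pixel_pitch,
               ambient_C = video$ambient,
               exposure_start_frame = video$exposure_window[1],
               exposure_end_frame = video$exposure_window[2])
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_thermal
#' @return `read_thermal()` returns a [thermal_video()]
#' @export
read_thermal <- function(path) {
  pages <- read_tiff_pages(path)
  meta <- read_sidecar(path, required = c("fps", "pixel_pitch_um", "ambient_C",
                                          "exposure_start_frame", "exposure_end_frame"))
  if (!is.numeric(meta$fps) || meta$fps <= 0)
    .ll_error("sidecar fps must be > 0", "laserlesion_schema_error")
  d <- dim(pages[[1]])
  frames <- array(NA_real_, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  bad <- which(vapply(pages, function(p) any(!is.finite(p)), logical(1)))
  if (length(bad))
    .ll_error(paste0("NaN/Inf temperatures in frame(s): ", paste(bad - 1L, collapse = ", ")),
              "laserlesion_validation_error")
  thermal_video(frames, fps = meta$fps, pixel_pitch = meta$pixel_pitch_um,
                ambient = meta$ambient_C,
                exposure_window = c(meta$exposure_start_frame, meta$exposure_end_frame))
}

#' Exposure records
#'
#' One row per laser exposure: wavelength (nm), irradiance (W cm^-2), duration
#' (s), beam diameter (um), and the binary damage outcome. `outcome` is "0",
#' "1" or "excluded"; excluded wells carry an `exclusion_reason`.
#'
#' @param wavelength_nm,irradiance_W_cm2,duration_s,beam_diameter_um numeric
#' @param outcome character vector in `c("0", "1", "excluded")` (0/1 numerics
#'   are accepted and converted)
#' @param exclusion_reason optional character, NA when not excluded
#' @return data.frame of class `exposure_records`
#' @export
exposure_records <- function(wavelength_nm, irradiance_W_cm2, duration_s,
                             beam_diameter_um, outcome,
                             exclusion_reason = NA_character_) {
  outcome <- as.character(outcome)
  df <- data.frame(wavelength_nm = as.numeric(wavelength_nm),
                   irradiance_W_cm2 = as.numeric(irradiance_W_cm2),
                   duration_s = as.numeric(duration_s),
                   beam_diameter_um = as.numeric(beam_diameter_um),
                   outcome = outcome,
                   exclusion_reason = as.character(exclusion_reason),
                   stringsAsFactors = FALSE)
  validate_exposure_records(df)
  class(df) <- c("exposure_records", "data.frame")
  df
}

validate_exposure_records <- function(df) {
  bad <- which(!(df$outcome %in% c("0", "1", "excluded")))
  if (length(bad))
    .ll_error(paste0("invalid outcome at row(s): ", paste(bad, collapse = ", "),
                     " (must be 0, 1 or excluded)"), "laserlesion_validation_error")
  bad <- which(!is.finite(df$irradiance_W_cm2) | df$irradiance_W_cm2 < 0)
  if (length(bad))
    .ll_error(paste0("negative or non-finite irradiance at row(s): ",
                     paste(bad, collapse = ", ")), "laserlesion_validation_error")
  bad <- which(!is.finite(df$duration_s) | df$duration_s <= 0)
  if (length(bad))
    .ll_error(paste0("non-positive duration at row(s): ", paste(bad, collapse = ", ")),
              "laserlesion_validation_error")
  invisible(df)
}

#' Write / read exposure logs as CSV
#'
#' Columns: `wavelength_nm, irradiance_W_cm2, duration_s, beam_diameter_um,
#' outcome, exclusion_reason`.
#'
#' @param records an [exposure_records()] data.frame
#' @param path CSV path
#' @export
write_exposure_log <- function(records, path) {
  validate_exposure_records(records)
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_exposure_log
#' @export
read_exposure_log <- function(path) {
  if (!file.exists(path)) .ll_error(paste0("file not found: ", path), "laserlesion_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(outcome = "character"))
  required <- c("wavelength_nm", "irradiance_W_cm2", "duration_s",
                "beam_diameter_um", "outcome")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .ll_error(paste0("exposure log missing column(s): ", paste(missing, collapse = ", ")),
              "laserlesion_schema_error")
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- NA_character_
  df$exclusion_reason[df$exclusion_reason %in% ""] <- NA_character_
  exposure_records(df$wavelength_nm, df$irradiance_W_cm2, df$duration_s,
                   df$beam_diameter_um, df$outcome, df$exclusion_reason)
}
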