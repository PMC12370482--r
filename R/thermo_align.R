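# Fusion of damage masks with thermal video: hotspot location, mask
# registration (flip / quarter-turn / scale / translate), boundary-ring
# extraction, minimum-boundary-SD mask selection, and threshold-temperature
# histories. The steady-state read-out window is the final 10% of the
# exposure frames throughout.

steady_window_frames <- function(video) {
  ew <- video$exposure_window          # 0-based half-open
  n_exp <- ew[2] - ew[1]
  n_avg <- max(1L, floor(0.1 * n_exp))
  (ew[2] - n_avg + 1L):ew[2]           # 1-based frame indices
}

steady_mean_frame <- function(video) {
  fr <- steady_window_frames(video)
  if (length(fr) == 1L) video$frames[fr, , ] else
    apply(video$frames[fr, , , drop = FALSE], c(2, 3), mean)
}

#' Locate the thermogram hotspot
#'
#' Argmax of the frame averaged over the last 10% of the exposure window
#' (temporal averaging suppresses single-frame noise). Ties break to the
#' lexicographically smallest `(row, col)`.
#'
#' @param video a [thermal_video()]
#' @return integer `(row, col)`, 1-based
#' @export
find_hotspot <- function(video) {
  stopifnot(inherits(video, "thermal_video"))
  avg <- steady_mean_frame(video)
  if (all(!is.finite(avg))) .ll_error("all-NaN steady window", "laserlesion_validation_error")
  hits <- which(avg == max(avg, na.rm = TRUE), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(hits[1, ])
}

#' Register a damage mask onto thermal-pixel coordinates
#'
#' Nearest-neighbour rescale by the pixel-pitch ratio, then the configured
#' flips and quarter-turn rotations, then translation of the mask centroid to
#' the thermogram hotspot. The transform vocabulary is deliberately restricted
#' to flips, 90-degree rotations, uniform scale and translation.
#'
#' @param mask a [finalize_mask()] result (`damage_mask`)
#' @param video a [thermal_video()]
#' @param orientation list with `flip_h`, `flip_v` (logicals) and `rotations`
#'   (quarter turns, 0-3); instrument-specific, defaults to identity
#' @return object of class `registered_mask`: `mask` (logical matrix in thermal
#'   frame dimensions), `transform`, `stringency_index`
#' @export
register_mask <- function(mask, video,
                          orientation = list(flip_h = FALSE, flip_v = FALSE, rotations = 0L)) {
  stopifnot(inherits(mask, "damage_mask"), inherits(video, "thermal_video"))
  scale <- mask$pixel_pitch / video$pixel_pitch
  m <- mask$mask
  # nearest-neighbour resample
  nr2 <- max(1L, round(nrow(m) * scale)); nc2 <- max(1L, round(ncol(m) * scale))
  ri <- pmin(pmax(round((seq_len(nr2) - 0.5) / scale + 0.5), 1L), nrow(m))
  ci <- pmin(pmax(round((seq_len(nc2) - 0.5) / scale + 0.5), 1L), ncol(m))
  m <- m[ri, ci, drop = FALSE]
  if (isTRUE(orientation$flip_h)) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (isTRUE(orientation$flip_v)) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  rot <- (orientation$rotations %||% 0L) %% 4L
  for (k in seq_len(rot)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  d <- dim(video$frames)[2:3]
  if (nrow(m) > d[1] || ncol(m) > d[2])
    .ll_error("scaled mask exceeds thermal frame", "laserlesion_out_of_frame_error")
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) .ll_error("registered mask is empty", "laserlesion_empty_mask_error")
  centroid <- colMeans(idx)
  hot <- find_hotspot(video)
  shift <- round(hot - centroid)
  out <- matrix(FALSE, d[1], d[2])
  r2 <- idx[, 1] + shift[1]; c2 <- idx[, 2] + shift[2]
  if (any(r2 < 1 | r2 > d[1] | c2 < 1 | c2 > d[2]))
    .ll_error("translated mask exceeds thermal frame", "laserlesion_out_of_frame_error")
  out[cbind(r2, c2)] <- TRUE
  structure(list(mask = out,
                 transform = list(scale = scale, flip_h = isTRUE(orientation$flip_h),
                                  flip_v = isTRUE(orientation$flip_v), rotations = rot,
                                  translation = as.integer(shift)),
                 stringency_index = mask$stringency_index),
            class = "registered_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-pixel-wide boundary ring of a registered mask
#'
#' `ring = mask XOR erode(mask, 1)` with the 3x3 (8-connected) structuring
#' element.
#'
#' @param rmask a `registered_mask` (or any object with a logical `$mask`)
#' @return object of class `boundary_ring`: `pixels` (n x 2 matrix of
#'   (row, col)), `mask` (logical ring matrix)
#' @export
boundary_ring <- function(rmask) {
  m <- if (is.list(rmask)) rmask$mask else rmask
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0 || diff(range(idx[, 1])) < 2 || diff(range(idx[, 2])) < 2)
    .ll_error("mask too small for a boundary ring (needs >= 3x3 extent)",
              "laserlesion_degenerate_mask_error")
  ring <- (m != 0) & !binary_erode(m, 1L)
  if (!any(ring)) .ll_error("boundary ring is empty", "laserlesion_degenerate_mask_error")
  structure(list(pixels = which(ring, arr.ind = TRUE), mask = ring),
            class = "boundary_ring")
}

ring_stats <- function(frame, ring) {
  v <- frame[ring$pixels]
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Select the mask whose boundary sits on the tightest isotherm
#'
#' For each candidate, the SD of temperatures over its boundary ring is
#' computed on the frame averaged over the last 10% of the exposure window;
#' the candidate with the smallest SD wins (a boundary lying on an isotherm
#' has SD close to camera noise only). Ties break to the lowest stringency
#' index.
#'
#' @param masks list of `registered_mask`
#' @param video a [thermal_video()]
#' @return list: `chosen` (the winning `registered_mask`), `report`
#'   (data.frame of stringency_index, ring_sd, ring_mean, n_ring_px)
#' @export
select_mask <- function(masks, video) {
  stopifnot(length(masks) >= 1)
  avg <- steady_mean_frame(video)
  rows <- lapply(masks, function(m) {
    st <- ring_stats(avg, boundary_ring(m))
    data.frame(stringency_index = m$stringency_index,
               ring_mean = st["mean"], ring_sd = st["sd"],
               n_ring_px = nrow(boundary_ring(m)$pixels))
  })
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  best <- order(report$ring_sd, report$stringency_index)[1]
  list(chosen = masks[[best]], report = report)
}

#' Extract the threshold-temperature history for a boundary ring
#'
#' Per-frame ring mean and SD over the whole video; the threshold peak
#' temperature is the ring mean averaged over the last 10% of the exposure
#' window, and the centre peak temperature is the hotspot pixel averaged over
#' the same window. Temperature rises subtract the sidecar ambient.
#'
#' @param video a [thermal_video()]
#' @param ring a [boundary_ring()]
#' @return object of class `threshold_temperature_result` with fields
#'   `per_frame` (data.frame: frame, ring_mean, ring_sd),
#'   `threshold_peak_temperature`, `threshold_peak_dT`,
#'   `center_peak_temperature`, `center_peak_dT`, `ambient`
#' @export
extract_threshold_history <- function(video, ring) {
  stopifnot(inherits(video, "thermal_video"), inherits(ring, "boundary_ring"))
  ew <- video$exposure_window
  if ((ew[2] - ew[1]) < 10)
    .ll_error("exposure window shorter than 10 frames", "laserlesion_window_error")
  n <- dim(video$frames)[1]
  px <- ring$pixels
  stats <- t(vapply(seq_len(n), function(i) ring_stats(video$frames[i, , ], ring),
                    numeric(2)))
  per_frame <- data.frame(frame = seq_len(n) - 1L, ring_mean = stats[, 1],
                          ring_sd = stats[, 2])
  fr <- steady_window_frames(video)
  thr_peak <- mean(stats[fr, 1])
  hot <- find_hotspot(video)
  ctr_peak <- mean(video$frames[fr, hot[1], hot[2]])
  structure(list(per_frame = per_frame,
                 threshold_peak_temperature = thr_peak,
                 threshold_peak_dT = thr_peak - video$ambient,
                 center_peak_temperature = ctr_peak,
                 center_peak_dT = ctr_peak - video$ambient,
                 ambient = video$ambient),
            class = "threshold_temperature_result")
}

#' @export
print.threshold_temperature_result <- function(x, ...) {
  cat(sprintf("<threshold_temperature_result> boundary %.2f C (dT %.2f), center %.2f C (dT %.2f)\n",
              x$threshold_peak_temperature, x$threshold_peak_dT,
              x$center_peak_temperature, x$center_peak_dT))
  invisible(x)
}

#' Irradiance -> steady-state temperature standard curve
#'
#' Ordinary least squares of centre peak temperature on irradiance, with
#' algebraic inverse prediction ("what irradiance produces temperature T?").
#'
#' @param irradiance vector, W cm^-2 (at least 2 distinct values)
#' @param temperature vector, degrees C
#' @return object of class `thermal_curve`: `slope`, `intercept`,
#'   `r_squared`, and functions `predict_temperature(E)`,
#'   `predict_irradiance(T)`
#' @export
fit_thermal_curve <- function(irradiance, temperature) {
  if (length(unique(irradiance)) < 2)
    .ll_error("need at least 2 distinct irradiances", "laserlesion_rank_error")
  fit <- lm(temperature ~ irradiance)
  b <- unname(coef(fit))
  ss_tot <- sum((temperature - mean(temperature))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(slope = b[2], intercept = b[1], r_squared = r2,
                 predict_temperature = function(E) b[1] + b[2] * E,
                 predict_irradiance = function(temp) (temp - b[1]) / b[2]),
            class = "thermal_curve")
}
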