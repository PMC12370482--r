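# Damage-mask construction from live/dead fluorescence.
#
# Stages mirror the original lesion-mask recipe: split channels and subtract
# red from green (bleed-through), enhance contrast, threshold with the
# gradient-weighted quadtree RATS algorithm at four stringencies, clean each
# mask with 10 erosions + 10 dilations, and finalise to a single contiguous,
# hole-free region. The whole pipeline is deterministic given the image and
# schedule.

#' RATS threshold parameters
#'
#' @param noise_sd intensity-noise SD used to gate gradients; `NULL` estimates
#'   it from the image as `1.4826 * MAD` of the Sobel gradient magnitude
#' @param lambda_factor gradient gate multiplier (gradients below
#'   `lambda_factor * noise_sd` get zero weight)
#' @param min_leaf quadtree leaf side in pixels; must be a power of 2, >= 2.
#'   Larger leaves mean coarser local detail (lower stringency).
#' @return object of class `rats_params`
#' @export
rats_params <- function(noise_sd = NULL, lambda_factor = 3, min_leaf = 8L) {
  if (!is.null(noise_sd) && noise_sd < 0)
    .ll_error("noise_sd must be >= 0", "laserlesion_parameter_error")
  if (lambda_factor <= 0) .ll_error("lambda_factor must be > 0", "laserlesion_parameter_error")
  ml <- as.integer(min_leaf)
  if (ml < 2L || bitwAnd(ml, ml - 1L) != 0L)
    .ll_error("min_leaf must be a power of 2 and >= 2", "laserlesion_parameter_error")
  structure(list(noise_sd = noise_sd, lambda_factor = lambda_factor, min_leaf = ml),
            class = "rats_params")
}

#' Default four-step stringency schedule
#'
#' Mask 1 (stringency 0) has the finest leaf and most edge detail; each later
#' mask doubles the leaf size ("larger minimum feature size").
#'
#' @param min_leaves integer vector of 4 strictly increasing leaf sides
#' @param lambda_factor shared gradient gate multiplier
#' @return list of 4 [rats_params()]
#' @export
default_rats_schedule <- function(min_leaves = c(8L, 16L, 32L, 64L), lambda_factor = 3) {
  lapply(min_leaves, function(ml) rats_params(lambda_factor = lambda_factor, min_leaf = ml))
}

#' Subtract bleed-through and derive the damage signal
#'
#' Computes the corrected live signal `L = max(green - red, 0)` and the
#' damage signal `D = max(L) - L` (damage is where live signal is absent).
#' `D` is the input to the mask pipeline.
#'
#' @param img a [two_channel_image()]
#' @return list with matrices `live` and `damage`
#' @export
correct_bleedthrough <- function(img) {
  stopifnot(inherits(img, "two_channel_image"))
  L <- pmax(img$green - img$red, 0)
  if (max(L) <= 0)
    .ll_error("degenerate input: corrected live signal is identically zero",
              "laserlesion_degenerate_error")
  list(live = L, damage = max(L) - L)
}

#' Linear contrast enhancement with tail saturation
#'
#' Rescales to [0, 1], clipping `saturated_fraction` of pixels at each tail.
#' Order-preserving on unclipped pixels. A constant image is returned
#' unchanged with a warning.
#'
#' @param img numeric matrix
#' @param saturated_fraction proportion clipped at each tail, in [0, 0.5)
#' @return matrix in [0, 1]
#' @export
enhance_contrast <- function(img, saturated_fraction = 0.0035) {
  if (saturated_fraction < 0 || saturated_fraction >= 0.5)
    .ll_error("saturated_fraction must be in [0, 0.5)", "laserlesion_parameter_error")
  q <- quantile(img, c(saturated_fraction, 1 - saturated_fraction), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: contrast enhancement is a no-op")
    return(img)
  }
  out <- (img - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Estimate intensity noise from gradient statistics
#'
#' `1.4826 * MAD` of the Sobel gradient magnitude over the image border margin
#' (outer 10% of rows/cols), which is assumed lesion-free.
#' @param img numeric matrix
#' @return scalar noise SD estimate
#' @export
estimate_noise_sd <- function(img) {
  g <- sobel_magnitude(img)
  mr <- max(2L, round(nrow(g) * 0.1)); mc <- max(2L, round(ncol(g) * 0.1))
  border <- c(g[c(seq_len(mr), nrow(g) - seq_len(mr) + 1L), ],
              g[, c(seq_len(mc), ncol(g) - seq_len(mc) + 1L)])
  mad(border)
}

#' Gradient-weighted quadtree automatic threshold (RATS)
#'
#' Pixels are weighted by squared Sobel gradient magnitude where the gradient
#' exceeds `lambda_factor * noise_sd` (zero elsewhere). The image is tiled by
#' a quadtree down to `min_leaf`; each leaf with total weight above the
#' significance floor gets the weighted-mean threshold
#' `T = sum(w f) / sum(w)`; leaves without significant weight inherit the
#' weighted mean of their deepest significant ancestor. The per-pixel
#' threshold surface is bilinear-interpolated between leaf centres, and the
#' mask is `f >= threshold`.
#'
#' @param img numeric matrix (the damage signal; high values = lesion)
#' @param params a [rats_params()]
#' @return logical mask matrix, with attributes `threshold_surface` and
#'   `noise_sd`
#' @export
rats_threshold <- function(img, params = rats_params()) {
  stopifnot(inherits(params, "rats_params"))
  nr <- nrow(img); nc <- ncol(img)
  ml <- params$min_leaf
  if (min(nr, nc) < ml)
    .ll_error("image sides must be at least min_leaf", "laserlesion_parameter_error")
  sigma <- if (is.null(params$noise_sd)) estimate_noise_sd(img) else params$noise_sd
  g <- sobel_magnitude(img)
  gate <- params$lambda_factor * sigma
  w <- ifelse(g > gate, g^2, 0)
  # significance floor: the equivalent of min_leaf pixels of gate-level gradient
  floor_w <- gate^2 * ml
  if (floor_w <= 0) floor_w <- .Machine$double.eps

  # leaf-cell aggregation (cells of ml x ml; edge cells truncated)
  ncr <- ceiling(nr / ml); ncc <- ceiling(nc / ml)
  cell_r <- (seq_len(nr) - 1L) %/% ml + 1L
  cell_c <- (seq_len(nc) - 1L) %/% ml + 1L
  agg <- function(m) {
    t(rowsum(t(rowsum(m, cell_r, reorder = TRUE)), cell_c, reorder = TRUE))
  }
  Sw <- agg(w); Swf <- agg(w * img)
  # pyramid: pad each level to even dims, sum 2x2 blocks
  levels <- list(list(Sw = Sw, Swf = Swf))
  while (nrow(levels[[length(levels)]]$Sw) > 1 || ncol(levels[[length(levels)]]$Sw) > 1) {
    cur <- levels[[length(levels)]]
    a <- cur$Sw; b <- cur$Swf
    if (nrow(a) %% 2) { a <- rbind(a, 0); b <- rbind(b, 0) }
    if (ncol(a) %% 2) { a <- cbind(a, 0); b <- cbind(b, 0) }
    ridx <- (seq_len(nrow(a)) - 1L) %/% 2L + 1L
    cidx <- (seq_len(ncol(a)) - 1L) %/% 2L + 1L
    shrink <- function(m) t(rowsum(t(rowsum(m, ridx)), cidx))
    levels[[length(levels) + 1L]] <- list(Sw = shrink(a), Swf = shrink(b))
  }
  root <- levels[[length(levels)]]
  if (root$Sw[1, 1] <= floor_w)
    .ll_error("no significant edges found (flat image?)", "laserlesion_no_edges_error")
  # top-down: each cell takes its own weighted mean if significant, else parent's
  Tlev <- root$Swf / root$Sw
  for (li in rev(seq_len(length(levels) - 1L))) {
    cur <- levels[[li]]
    parentT <- Tlev
    nrl <- nrow(cur$Sw); ncl <- ncol(cur$Sw)
    pr <- (seq_len(nrl) - 1L) %/% 2L + 1L
    pc <- (seq_len(ncl) - 1L) %/% 2L + 1L
    inherited <- parentT[pr, pc, drop = FALSE]
    own <- cur$Swf / pmax(cur$Sw, .Machine$double.xmin)
    Tlev <- ifelse(cur$Sw > floor_w, own, inherited)
  }
  # bilinear interpolation between leaf-cell centres
  cell_center <- function(n_cells, n_px) {
    start <- (seq_len(n_cells) - 1L) * ml + 1L
    end <- pmin(seq_len(n_cells) * ml, n_px)
    (start + end) / 2
  }
  centers_r <- cell_center(ncr, nr)
  centers_c <- cell_center(ncc, nc)
  interp1 <- function(centers, n) {
    x <- seq_len(n)
    i <- findInterval(x, centers, all.inside = TRUE)
    x0 <- centers[i]; x1 <- centers[i + 1L]
    tfrac <- (x - x0) / (x1 - x0)
    tfrac[tfrac < 0] <- 0; tfrac[tfrac > 1] <- 1
    list(i = i, t = tfrac)
  }
  if (ncr == 1L) { ir <- list(i = rep(1L, nr), t = rep(0, nr)) } else ir <- interp1(centers_r, nr)
  if (ncc == 1L) { ic <- list(i = rep(1L, nc), t = rep(0, nc)) } else ic <- interp1(centers_c, nc)
  i2r <- pmin(ir$i + 1L, ncr); i2c <- pmin(ic$i + 1L, ncc)
  T00 <- Tlev[ir$i, ic$i, drop = FALSE]; T01 <- Tlev[ir$i, i2c, drop = FALSE]
  T10 <- Tlev[i2r, ic$i, drop = FALSE]; T11 <- Tlev[i2r, i2c, drop = FALSE]
  tr <- matrix(ir$t, nr, nc); tc <- matrix(ic$t, nr, nc, byrow = TRUE)
  surface <- (1 - tr) * (1 - tc) * T00 + (1 - tr) * tc * T01 +
    tr * (1 - tc) * T10 + tr * tc * T11
  dimnames(surface) <- NULL
  mask <- img >= surface
  attr(mask, "threshold_surface") <- surface
  attr(mask, "noise_sd") <- sigma
  mask
}

#' Morphological mask cleaning (opening)
#'
#' `iterations` erosions followed by `iterations` dilations with the 3x3
#' square structuring element. Removes components thinner than about
#' `2 * iterations` px while leaving large convex regions nearly unchanged.
#'
#' @param mask logical/0-1 matrix
#' @param iterations default 10
#' @return logical matrix
#' @export
clean_mask <- function(mask, iterations = 10L) {
  m <- binary_erode(mask, iterations)
  if (!any(m))
    .ll_error("mask emptied by cleaning (try a lower stringency)",
              "laserlesion_empty_mask_error")
  binary_dilate(m, iterations)
}

#' Finalise a mask to one contiguous hole-free lesion region
#'
#' Keeps the principal 8-connected component (largest area; among components
#' within 50% of the largest, the one whose centroid is nearest the image
#' centre) and fills interior holes. If any discarded component exceeds 25% of
#' the principal area the result is flagged `needs_review` instead of being
#' silently trusted (this replaces the original manual-inspection step).
#'
#' @param mask logical/0-1 matrix
#' @param stringency_index integer 0-3 recorded in the result
#' @param pixel_pitch micrometres per pixel
#' @param provenance free-form parameter record
#' @return object of class `damage_mask`: fields `mask`, `stringency_index`,
#'   `pixel_pitch`, `needs_review`, `provenance`
#' @export
finalize_mask <- function(mask, stringency_index = 0L, pixel_pitch = 1,
                          provenance = list()) {
  if (!any(mask != 0)) .ll_error("empty mask", "laserlesion_empty_mask_error")
  lab <- label_components(mask, connectivity = 8)
  n <- attr(lab, "n")
  areas <- tabulate(lab[lab > 0], nbins = n)
  cand <- which(areas >= 0.5 * max(areas))
  if (length(cand) > 1) {
    ctr <- c((nrow(mask) + 1) / 2, (ncol(mask) + 1) / 2)
    d <- vapply(cand, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      sqrt((mean(idx[, 1]) - ctr[1])^2 + (mean(idx[, 2]) - ctr[2])^2)
    }, numeric(1))
    principal <- cand[which.min(d)]
  } else principal <- cand
  needs_review <- any(areas[-principal] > 0.25 * areas[principal])
  out <- fill_holes(lab == principal)
  structure(list(mask = out, stringency_index = as.integer(stringency_index),
                 pixel_pitch = pixel_pitch, needs_review = needs_review,
                 provenance = provenance),
            class = "damage_mask")
}

#' @export
print.damage_mask <- function(x, ...) {
  cat(sprintf("<damage_mask> stringency %d, area %d px%s\n", x$stringency_index,
              sum(x$mask), if (x$needs_review) " [needs_review]" else ""))
  invisible(x)
}

#' Build the four-stringency mask set
#'
#' Applies [rats_threshold()], [clean_mask()] and [finalize_mask()] at each of
#' the four schedule entries. Individual stringency failures (no edges, mask
#' emptied) are tolerated; an error is raised only if all four fail.
#'
#' @param damage_signal numeric matrix (from [correct_bleedthrough()] +
#'   [enhance_contrast()])
#' @param schedule list of 4 [rats_params()] with strictly increasing
#'   `min_leaf`
#' @param pixel_pitch micrometres per pixel, recorded in each mask
#' @param clean_iterations erosion/dilation count (default 10)
#' @return list of [finalize_mask()] results (possibly fewer than 4), each with
#'   `stringency_index` 0-3; attribute `failures` records skipped stringencies
#' @export
build_mask_set <- function(damage_signal, schedule = default_rats_schedule(),
                           pixel_pitch = 1, clean_iterations = 10L) {
  if (length(schedule) != 4)
    .ll_error("schedule must hold 4 parameter sets", "laserlesion_parameter_error")
  leaves <- vapply(schedule, function(p) p$min_leaf, integer(1))
  if (any(diff(leaves) <= 0))
    .ll_error("schedule min_leaf must be strictly increasing", "laserlesion_parameter_error")
  masks <- list(); failures <- character(0)
  for (i in seq_along(schedule)) {
    res <- tryCatch({
      m <- rats_threshold(damage_signal, schedule[[i]])
      m <- clean_mask(m, clean_iterations)
      finalize_mask(m, stringency_index = i - 1L, pixel_pitch = pixel_pitch,
                    provenance = list(min_leaf = schedule[[i]]$min_leaf,
                                      lambda_factor = schedule[[i]]$lambda_factor,
                                      noise_sd = schedule[[i]]$noise_sd))
    }, laserlesion_error = function(e) e)
    if (inherits(res, "damage_mask")) masks[[length(masks) + 1L]] <- res
    else failures <- c(failures, sprintf("stringency %d: %s", i - 1L, conditionMessage(res)))
  }
  if (!length(masks))
    .ll_error(paste0("all stringencies failed: ", paste(failures, collapse = "; ")),
              "laserlesion_all_masks_failed_error")
  attr(masks, "failures") <- failures
  masks
}

#' Fluorescence image to mask set, end to end
#'
#' Convenience wrapper: bleed-through correction, contrast enhancement,
#' [build_mask_set()].
#'
#' @inheritParams correct_bleedthrough
#' @inheritParams build_mask_set
#' @param saturated_fraction for [enhance_contrast()]
#' @return as [build_mask_set()]
#' @export
mask_pipeline <- function(img, schedule = default_rats_schedule(),
                          saturated_fraction = 0.0035, clean_iterations = 10L) {
  sig <- correct_bleedthrough(img)
  d <- enhance_contrast(sig$damage, saturated_fraction)
  build_mask_set(d, schedule, pixel_pitch = img$pixel_pitch,
                 clean_iterations = clean_iterations)
}
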