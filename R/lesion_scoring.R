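# Automated binary lesion scoring.
#
# Photochemical positives: an identifiably circular cluster of at least five
# dead cells, centred in and not exceeding the laser footprint. Photothermal
# positives: a contiguous dead region overlapping the beam centre; a sublethal
# halo without central red staining scores negative. QC heuristics flag wells
# that a human scorer would have excluded.

robust_threshold <- function(channel, k = 5) {
  median(channel) + k * mad(channel)
}

#' Detect dead-cell (red nucleus) centroids
#'
#' Connected components of the red channel above `median + 5 * MAD`, refined
#' with a per-component cut at 30% of the component peak (removing the optical
#' blur skirt so touching nuclei separate), then filtered to nucleus-scale
#' areas. Components above the upper area cut (merged nuclei, contiguous dead
#' sheets) are not returned as centroids but are preserved, with an area-based
#' nucleus-count estimate, in the `components` attribute so callers can reason
#' about dense lesions.
#'
#' @param img a [two_channel_image()]
#' @param area_range_um2 accepted centroid component area, square micrometres
#'   (default 20-400)
#' @return n x 2 matrix of centroids (row, col), 1-based pixels; attributes
#'   `threshold` (intensity cut) and `components` (data.frame with one row per
#'   red component of at least the minimum area: centroid, `area_um2`, and
#'   `est_n`, the estimated nucleus count `max(1, round(area / single))` using
#'   the median single-nucleus area)
#' @export
detect_dead_cells <- function(img, area_range_um2 = c(20, 400)) {
  stopifnot(inherits(img, "two_channel_image"))
  if (mean(img$red >= 0.45 * 65535) >= 0.5)
    .ll_error("red channel saturated (>= 50% of pixels at high intensity)",
              "laserlesion_qc_error")
  thr <- robust_threshold(img$red)
  bw <- img$red > thr
  if (mean(bw) >= 0.5)
    .ll_error("red channel saturated (>= 50% of pixels above threshold)",
              "laserlesion_qc_error")
  empty <- function() {
    out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    attr(out, "threshold") <- thr
    attr(out, "components") <- data.frame(row = numeric(0), col = numeric(0),
                                          area_um2 = numeric(0), est_n = integer(0))
    out
  }
  if (!any(bw)) return(empty())
  # refine: cut each component at 30% of its peak to drop the blur skirt
  lab0 <- label_components(bw, connectivity = 8)
  peaks <- vapply(seq_len(attr(lab0, "n")), function(k) max(img$red[lab0 == k]),
                  numeric(1))
  cutmap <- matrix(0, nrow(bw), ncol(bw))
  cutmap[lab0 > 0] <- pmax(thr, 0.3 * peaks[lab0[lab0 > 0]])
  bw <- img$red > cutmap & lab0 > 0
  if (!any(bw)) return(empty())
  lab <- label_components(bw, connectivity = 8)
  n <- attr(lab, "n")
  px_area <- img$pixel_pitch^2
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  areas <- tabulate(labs, nbins = n) * px_area
  cent <- t(vapply(seq_len(n), function(k) {
    sel <- labs == k
    c(mean(idx[sel, 1]), mean(idx[sel, 2]))
  }, numeric(2)))
  single_like <- areas >= area_range_um2[1] & areas <= area_range_um2[2]
  single_area <- if (any(single_like)) median(areas[single_like]) else 95
  comp_keep <- areas >= area_range_um2[1]
  comps <- data.frame(row = cent[comp_keep, 1], col = cent[comp_keep, 2],
                      area_um2 = areas[comp_keep],
                      est_n = pmax(1L, as.integer(round(areas[comp_keep] / single_area))))
  out <- cent[single_like, , drop = FALSE]
  colnames(out) <- c("row", "col")
  attr(out, "threshold") <- thr
  attr(out, "components") <- comps
  out
}

hull_metrics <- function(pts) {
  # circularity 4*pi*A/P^2 and max diameter of the convex hull of points
  if (nrow(pts) < 3) return(list(circularity = NA_real_, max_diameter = if (nrow(pts) == 2)
    sqrt(sum((pts[1, ] - pts[2, ])^2)) else 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  nxt <- c(2:nh, 1)
  area <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  per <- sum(sqrt(rowSums((hp - hp[nxt, , drop = FALSE])^2)))
  dmax <- max(dist(hp))
  list(circularity = if (per > 0) 4 * pi * area / per^2 else NA_real_,
       max_diameter = dmax)
}

beam_center_px <- function(img, beam) {
  if (!is.null(beam$center)) return(beam$center)
  bc <- img$metadata$beam_center
  if (!is.null(bc)) return(unlist(bc) + 1)  # sidecar is 0-based
  c((nrow(img$green) + 1) / 2, (ncol(img$green) + 1) / 2)
}

score_report <- function(outcome, phenotype, n_dead, diameter_um, circularity,
                         reasons) {
  structure(list(outcome = outcome, phenotype = phenotype,
                 dead_cell_count_in_footprint = n_dead,
                 damage_extent_diameter_um = diameter_um,
                 circularity = circularity, reasons = reasons),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s (%s): %d dead in footprint, extent %.0f um%s\n",
              x$outcome, x$phenotype, x$dead_cell_count_in_footprint,
              x$damage_extent_diameter_um,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Score an image for photochemical damage
#'
#' Positive iff (a) at least `min_dead_cells` dead-cell centroids lie inside
#' the central `central_fraction` of the footprint radius, (b) the convex hull
#' of the in-footprint dead cells has circularity at least `circularity_min`,
#' and (c) the damage does not extend past the footprint: dead cells in the
#' annulus between `footprint_tolerance` and 2 footprint radii must stay below
#' `max(3, outside_fraction_max *` in-footprint count`)`. (A literal
#' hull-diameter-vs-footprint check is vacuous once the hull is restricted to
#' in-footprint cells, so the extent rule is implemented as this
#' outside-density check; a few spontaneous background deaths do not trip it.)
#'
#' @param img a [two_channel_image()]
#' @param beam a [beam_profile()]
#' @param min_dead_cells default 5
#' @param central_fraction default 0.5 ("the centre of that region")
#' @param circularity_min default 0.6 (proxy for "identifiable circular shape")
#' @param footprint_tolerance default 1.05 (absorbs discretisation)
#' @param outside_fraction_max default 0.2
#' @return a `score_report`
#' @export
score_photochemical <- function(img, beam, min_dead_cells = 5L,
                                central_fraction = 0.5, circularity_min = 0.6,
                                footprint_tolerance = 1.05,
                                outside_fraction_max = 0.2) {
  cent <- detect_dead_cells(img)
  comps <- attr(cent, "components")
  ctr <- beam_center_px(img, beam)
  foot_r_px <- beam$diameter_um / 2 / img$pixel_pitch
  # estimated nucleus counts by region, using all red components (merged
  # nuclei and dead sheets count by area)
  d_comp <- sqrt((comps$row - ctr[1])^2 + (comps$col - ctr[2])^2)
  n_central <- sum(comps$est_n[d_comp <= central_fraction * foot_r_px])
  n_foot <- sum(comps$est_n[d_comp <= foot_r_px])
  n_annulus <- sum(comps$est_n[d_comp > footprint_tolerance * foot_r_px &
                                 d_comp <= 2 * foot_r_px])
  reasons <- character(0)
  in_foot_pts <- comps[d_comp <= foot_r_px, c("row", "col"), drop = FALSE]
  hm <- hull_metrics(as.matrix(in_foot_pts))
  ext_um <- (hm$max_diameter %||% 0) * img$pixel_pitch
  if (n_central < min_dead_cells) reasons <- c(reasons, "min dead cells")
  if (!is.na(hm$circularity) && hm$circularity < circularity_min)
    reasons <- c(reasons, "not circular")
  if (n_annulus > max(3, outside_fraction_max * n_foot))
    reasons <- c(reasons, "exceeds footprint")
  score_report(if (length(reasons)) "negative" else "positive", "photochemical",
               n_foot, ext_um, hm$circularity, reasons)
}

#' Score an image for photothermal damage
#'
#' Positive iff a single connected dead region (dead-cell detections merged
#' over a cell-scale distance) overlaps the beam centre and covers at least
#' `min_area_cells` typical cell areas. Halo-only images (altered morphology
#' without central red staining) score negative.
#'
#' @param img a [two_channel_image()]
#' @param beam a [beam_profile()]
#' @param min_area_nuclei minimum red-stained core area, in nucleus areas
#'   (default 10; nucleus area 80 um^2). Nuclei in a thermal core touch and
#'   merge, so the rule works on stained area rather than counted centroids.
#' @param nucleus_area_um2 typical stained nucleus area (default 80 um^2)
#' @param merge_radius_um dilation radius used to connect adjacent dead nuclei
#'   into one region (default 15 um, about one cell diameter)
#' @param center_tolerance_um how close the dead region must come to the beam
#'   centre (default 50 um)
#' @return a `score_report`
#' @export
score_photothermal <- function(img, beam, min_area_nuclei = 10,
                               nucleus_area_um2 = 80, merge_radius_um = 15,
                               center_tolerance_um = 50) {
  stopifnot(inherits(img, "two_channel_image"))
  ctr <- beam_center_px(img, beam)
  red_bw <- img$red > robust_threshold(img$red)
  if (!any(red_bw)) {
    return(score_report("negative", "photothermal", 0L, 0, NA_real_,
                        "no dead cells"))
  }
  # merge red-stained nuclei into candidate regions
  merge_px <- max(1L, round(merge_radius_um / img$pixel_pitch / 2))
  bw <- binary_dilate(red_bw, merge_px)
  lab <- label_components(bw, connectivity = 8)
  n <- attr(lab, "n")
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  dctr <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  # red-stained area per region (undilated)
  red_area <- vapply(seq_len(n), function(k) {
    sel <- labs == k
    sum(red_bw[idx[sel, , drop = FALSE]])
  }, numeric(1)) * img$pixel_pitch^2
  dmin <- vapply(seq_len(n), function(k) min(dctr[labs == k]), numeric(1))
  # principal candidate: the largest stained region reaching the beam centre,
  # else the nearest one
  central <- which(dmin * img$pixel_pitch <= center_tolerance_um)
  k0 <- if (length(central)) central[which.max(red_area[central])] else which.min(dmin)
  reasons <- character(0)
  if (dmin[k0] * img$pixel_pitch > center_tolerance_um)
    reasons <- c(reasons, "no central dead region")
  if (red_area[k0] < min_area_nuclei * nucleus_area_um2)
    reasons <- c(reasons, "dead core too small")
  sel <- idx[labs == k0, , drop = FALSE]
  ext <- max(dist(sel[c(which.min(sel[, 1]), which.max(sel[, 1]),
                        which.min(sel[, 2]), which.max(sel[, 2])), , drop = FALSE]))
  n_nuclei <- round(red_area[k0] / nucleus_area_um2)
  score_report(if (length(reasons)) "negative" else "positive", "photothermal",
               as.integer(n_nuclei), ext * img$pixel_pitch, NA_real_, reasons)
}

#' Well-exclusion QC heuristics
#'
#' Best-effort automation of the manual exclusion rules: low live-cell
#' coverage outside the footprint suggests monolayer disruption; very large
#' bright objects outside the footprint suggest foreign material or pigment
#' clumps.
#'
#' @param img a [two_channel_image()]
#' @param beam optional [beam_profile()] defining the footprint (defaults to
#'   the sidecar geometry / image centre)
#' @param coverage_min minimum live coverage outside the footprint (default 0.6)
#' @param foreign_area_nuclei bright-object size cut in nucleus areas
#'   (default 10; nucleus area taken as 80 um^2)
#' @return `NULL` when the well passes, otherwise a character reason
#' @export
qc_exclusion <- function(img, beam = NULL, coverage_min = 0.6,
                         foreign_area_nuclei = 10) {
  stopifnot(inherits(img, "two_channel_image"))
  nr <- nrow(img$green); nc <- ncol(img$green)
  ctr <- if (!is.null(beam)) beam_center_px(img, beam) else c((nr + 1) / 2, (nc + 1) / 2)
  dia <- if (!is.null(beam)) beam$diameter_um else
    (img$metadata$beam_diameter_um %||% (min(nr, nc) * img$pixel_pitch / 2))
  foot_r_px <- dia / 2 / img$pixel_pitch
  outside <- radius_matrix(nr, nc, ctr) > foot_r_px
  gthr <- robust_threshold(img$green, k = 2)
  # "live" = clearly above background; use a low absolute floor when the
  # carpet dominates the image (median is then already signal)
  live <- img$green > min(gthr, max(img$green) * 0.15)
  if (mean(live[outside]) < coverage_min) return("monolayer disruption")
  nucleus_area_um2 <- 80
  for (ch in list(img$green, img$red)) {
    bright <- ch > robust_threshold(ch, k = 8)
    bright[!outside] <- FALSE
    if (any(bright)) {
      lab <- label_components(bright, connectivity = 8)
      areas <- tabulate(lab[lab > 0], nbins = attr(lab, "n")) * img$pixel_pitch^2
      if (any(areas > foreign_area_nuclei * nucleus_area_um2)) return("foreign material")
    }
  }
  NULL
}

#' @importFrom grDevices chull
#' @importFrom stats dist
NULL
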