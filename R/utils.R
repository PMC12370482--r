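# Internal raster helpers shared by the masking, alignment and simulation code.
# Conventions (used package-wide): matrices are indexed (row, col), 0-based
# coordinates in exported metadata, 1-based inside R; physical lengths in
# micrometres, temperatures in degrees Celsius, irradiance in W cm^-2.

#' @importFrom stats dnorm qnorm quantile median mad rbinom rpois runif rnorm
#'   pnorm binom.test glm binomial coef vcov qt pchisq uniroot lm t.test
#'   rlnorm integrate setNames
#' @importFrom utils read.csv write.csv
NULL

.ll_error <- function(msg, class, ...) {
  stop(structure(class = c(class, "laserlesion_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Shift a matrix by whole pixels, padding with a fill value
#' @noRd
mat_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 binary erosion/dilation (8-connected square structuring element, as in
# ImageJ's default binary erode/dilate). Pixels beyond the border count as
# background.
binary_erode <- function(mask, iterations = 1L) {
  m <- mask != 0
  for (i in seq_len(iterations)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc & mat_shift(m, dr, dc, fill = FALSE)
    }
    m <- acc
    if (!any(m)) break
  }
  m
}

binary_dilate <- function(mask, iterations = 1L) {
  m <- mask != 0
  for (i in seq_len(iterations)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc | mat_shift(m, dr, dc, fill = FALSE)
    }
    m <- acc
  }
  m
}

#' Label connected components of a binary matrix
#'
#' @param mask logical/0-1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background), attribute "n" = number of
#'   components, labels ordered by decreasing size.
#' @noRd
label_components <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) { attr(lab, "n") <- 0L; return(lab) }
  # map full-matrix index -> vertex id
  vid <- integer(nr * nc); vid[idx] <- seq_along(idx)
  offs <- if (connectivity == 8) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  } else list(c(1L, 0L), c(0L, 1L))
  ef <- integer(0); et <- integer(0)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- co + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    okn <- m[nidx]
    ef <- c(ef, vid[idx[ok][okn]])
    et <- c(et, vid[nidx[okn]])
  }
  g <- igraph::make_graph(rbind(ef, et), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  # relabel by decreasing component size
  ord <- order(comp$csize, decreasing = TRUE)
  relab <- integer(comp$no); relab[ord] <- seq_len(comp$no)
  lab[idx] <- relab[comp$membership]
  attr(lab, "n") <- comp$no
  lab
}

#' Fill interior holes: background 4-connected components not touching the
#' image border become foreground.
#' @noRd
fill_holes <- function(mask) {
  m <- mask != 0
  lab <- label_components(!m, connectivity = 4)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  hole <- lab > 0 & !(lab %in% border_labs)
  m | hole
}

#' Shift with replicate (clamped) padding
#' @noRd
mat_shift_rep <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) - dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) - dc, 1L), ncol(m))
  m[ri, ci]
}

#' Separable Gaussian blur with replicate padding
#' @noRd
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  for (along_rows in c(TRUE, FALSE)) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      d <- i - half - 1L
      acc <- acc + k[i] * if (along_rows) mat_shift_rep(m, d, 0) else mat_shift_rep(m, 0, d)
    }
    m <- acc
  }
  m
}

#' 3x3 Sobel gradient magnitude (replicate padding)
#' @noRd
sobel_magnitude <- function(m) {
  p <- function(dr, dc) mat_shift_rep(m, dr, dc)
  gx <- (p(-1, -1) + 2 * p(0, -1) + p(1, -1)) - (p(-1, 1) + 2 * p(0, 1) + p(1, 1))
  gy <- (p(-1, -1) + 2 * p(-1, 0) + p(-1, 1)) - (p(1, -1) + 2 * p(1, 0) + p(1, 1))
  sqrt(gx^2 + gy^2)
}

#' Rasterise filled disks onto a matrix by accumulation
#'
#' @param nr,nc output dimensions
#' @param rows,cols disk centres (may be fractional, 1-based)
#' @param radius_px scalar or per-disk radius
#' @param values per-disk intensity
#' @param op "max" keeps the per-pixel maximum, "add" accumulates
#' @noRd
paint_disks <- function(nr, nc, rows, cols, radius_px, values, op = "max") {
  out <- matrix(0, nr, nc)
  if (!length(rows)) return(out)
  radius_px <- rep_len(radius_px, length(rows))
  values <- rep_len(values, length(rows))
  for (i in seq_along(rows)) {
    r0 <- rows[i]; c0 <- cols[i]; rad <- radius_px[i]
    rr <- max(1L, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    inside <- d2 <= rad^2
    if (op == "max") {
      out[rr, cc][inside] <- pmax(out[rr, cc][inside], values[i])
    } else {
      out[rr, cc][inside] <- out[rr, cc][inside] + values[i]
    }
  }
  out
}

#' Matrix of radial distances (in pixels) from a centre
#' @noRd
radius_matrix <- function(nr, nc, center) {
  outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, "+")^0.5
}

#' Jaccard index between two binary masks
#' @export
#' @param a,b logical/0-1 matrices of identical dimensions
#' @return intersection-over-union in [0, 1] (1 when both are empty)
jaccard <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
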