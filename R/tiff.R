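# Minimal baseline TIFF codec.
#
# The pipeline's image contracts are multi-page TIFF (16-bit unsigned
# fluorescence, 32-bit float thermal stacks in degrees C). No TIFF package is
# available in the supported dependency set, so this file implements the small
# baseline subset needed: uncompressed, strip-based, chunky, single-sample
# grayscale pages. The reader accepts little- and big-endian files and multiple
# strips; the writer emits little-endian, one strip per page. Anything outside
# this subset is rejected with a format error rather than guessed at.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
                 strip_bytes = 279L, sample_format = 339L, samples_per_pixel = 277L)

#' Read a multi-page grayscale TIFF into a list of matrices
#'
#' Supports uncompressed baseline TIFF with 16-bit unsigned or 32-bit
#' IEEE-float samples, one sample per pixel.
#'
#' @param path file path
#' @return list of numeric matrices (row, col), one per page, with attribute
#'   `sample_format` ("uint16" or "float32")
#' @export
read_tiff_pages <- function(path) {
  if (!file.exists(path)) .ll_error(paste0("file not found: ", path), "laserlesion_io_error")
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 8) .ll_error("not a TIFF file (too short)", "laserlesion_format_error")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    .ll_error("not a TIFF file (bad byte-order mark)", "laserlesion_format_error")
  rint <- function(at, size, n = 1L) {
    # offsets/counts fit in signed 32-bit for the file sizes handled here
    readBin(raw_all[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4L)
  }
  magic <- rint(2, 2)
  if (magic != 42L) .ll_error("not a TIFF file (bad magic)", "laserlesion_format_error")
  ifd_off <- rint(4, 4)

  read_tag_values <- function(entry_at) {
    tag <- rint(entry_at, 2)
    type <- rint(entry_at + 2, 2)
    count <- rint(entry_at + 4, 4)
    size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
    if (is.na(size)) return(list(tag = tag, values = NULL))
    total <- size * count
    at <- if (total <= 4) entry_at + 8 else rint(entry_at + 8, 4)
    list(tag = tag, values = rint(at, size, count))
  }

  pages <- list()
  fmt <- NULL
  while (ifd_off != 0) {
    n_entries <- rint(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      tv <- read_tag_values(ifd_off + 2 + (i - 1) * 12)
      if (!is.null(tv$values)) tags[[as.character(tv$tag)]] <- tv$values
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (!is.null(default)) return(default)
        .ll_error(sprintf("TIFF page missing required tag %d", id), "laserlesion_format_error")
      }
      v
    }
    w <- need(TIFF_TAG$width); h <- need(TIFF_TAG$length)
    bits <- need(TIFF_TAG$bits)
    comp <- need(TIFF_TAG$compression, 1L)
    sfmt <- need(TIFF_TAG$sample_format, 1L)
    spp <- need(TIFF_TAG$samples_per_pixel, 1L)
    if (comp != 1L) .ll_error("unsupported TIFF: compressed data", "laserlesion_format_error")
    if (spp != 1L) .ll_error("unsupported TIFF: multi-sample pixels", "laserlesion_format_error")
    offs <- need(TIFF_TAG$strip_offsets); byts <- need(TIFF_TAG$strip_bytes)
    bps <- bits[1]
    kind <- if (bps == 16L && sfmt == 1L) "uint16"
      else if (bps == 32L && sfmt == 3L) "float32"
      else .ll_error(sprintf("unsupported TIFF sample type (%d-bit, format %d)", bps, sfmt),
                     "laserlesion_format_error")
    if (!is.null(fmt) && fmt != kind)
      .ll_error("TIFF pages have mixed sample formats", "laserlesion_format_error")
    fmt <- kind
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      chunk <- raw_all[(offs[s] + 1):(offs[s] + byts[s])]
      vals <- c(vals, if (kind == "uint16") {
        v <- readBin(chunk, "integer", n = byts[s] / 2L, size = 2L,
                     endian = endian, signed = FALSE)
        as.numeric(v)
      } else {
        readBin(chunk, "double", n = byts[s] / 4L, size = 4L, endian = endian)
      })
    }
    if (length(vals) != w * h)
      .ll_error("TIFF strip data does not match page dimensions", "laserlesion_format_error")
    # TIFF is row-major; R matrices are column-major
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rint(ifd_off + 2 + n_entries * 12, 4)
  }
  if (!length(pages)) .ll_error("TIFF contains no pages", "laserlesion_format_error")
  attr(pages, "sample_format") <- fmt
  pages
}

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param pages list of numeric matrices, identical dimensions
#' @param path output path
#' @param format "uint16" (values must be integers in 0..65535) or "float32"
#' @export
write_tiff_pages <- function(pages, path, format = c("uint16", "float32")) {
  format <- match.arg(format)
  if (!is.list(pages) || !length(pages)) .ll_error("pages must be a nonempty list", "laserlesion_io_error")
  dims <- dim(pages[[1]])
  for (p in pages) {
    if (!is.matrix(p) || !identical(dim(p), dims))
      .ll_error("all pages must be matrices with identical dimensions", "laserlesion_io_error")
    if (format == "uint16") {
      if (any(!is.finite(p)) || any(p < 0 | p > 65535) || any(p != round(p)))
        .ll_error("uint16 pages must hold integers in [0, 65535]", "laserlesion_io_error")
    }
  }
  h <- dims[1]; w <- dims[2]
  bps <- if (format == "uint16") 16L else 32L
  sfmt <- if (format == "uint16") 1L else 3L
  bytes_per <- bps / 8L
  strip_len <- as.integer(w * h * bytes_per)

  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeBin(charToRaw("II"), con); wint(42L, 2); wint(8L, 4)   # first IFD at byte 8

  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  pos <- 8L
  for (i in seq_along(pages)) {
    strip_off <- pos + ifd_size
    next_ifd <- if (i < length(pages)) strip_off + strip_len else 0L
    entry <- function(tag, type, count, value) {
      wint(tag, 2); wint(type, 2); wint(count, 4)
      if (type == 3L) { wint(value, 2); wint(0L, 2) } else wint(value, 4)
    }
    wint(n_entries, 2)
    entry(TIFF_TAG$width, 4L, 1L, w)
    entry(TIFF_TAG$length, 4L, 1L, h)
    entry(TIFF_TAG$bits, 3L, 1L, bps)
    entry(TIFF_TAG$compression, 3L, 1L, 1L)
    entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    entry(TIFF_TAG$strip_offsets, 4L, 1L, strip_off)
    entry(TIFF_TAG$samples_per_pixel, 3L, 1L, 1L)
    entry(TIFF_TAG$rows_per_strip, 4L, 1L, h)
    entry(TIFF_TAG$strip_bytes, 4L, 1L, strip_len)
    entry(TIFF_TAG$sample_format, 3L, 1L, sfmt)
    wint(next_ifd, 4)
    vals <- as.vector(t(pages[[i]]))  # row-major
    if (format == "uint16") {
      # writeBin has no unsigned 16-bit: wrap values >= 2^15 to signed range
      v <- as.integer(vals); v[v >= 32768L] <- v[v >= 32768L] - 65536L
      writeBin(v, con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    }
    pos <- strip_off + strip_len
  }
  invisible(path)
}
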