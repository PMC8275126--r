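# Minimal baseline-TIFF codec: little-endian, grayscale, uncompressed,
# one strip per page, 8/16-bit unsigned or 32-bit float, multi-page.
# Physical calibration travels in the ImageDescription tag as
# "pixel_size_um=<x>" / "frame_interval_min=<x>" lines. This covers the
# package's own fixtures and any plain uncompressed grayscale TIFF;
# compressed or tiled variants are rejected.

#' Write an image stack as a multi-page TIFF
#'
#' @param stack an [image_stack()], a single matrix, or a list of
#'   matrices (3D volumes are written plane-interleaved as z-pages per
#'   frame is not supported; pass 2D frames).
#' @param path output file.
#' @param pixel_size_um,frame_interval_min calibration; taken from the
#'   stack's attributes when present.
#' @param format `"float32"` (default), `"uint16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, pixel_size_um = NULL,
                             frame_interval_min = NULL, format = "float32") {
  if (inherits(stack, "image_stack")) {
    pixel_size_um <- pixel_size_um %||% attr(stack, "pixel_size_um")
    frame_interval_min <- frame_interval_min %||% attr(stack, "frame_interval_min")
    frames <- stack$frames
  } else if (is.matrix(stack)) {
    pixel_size_um <- pixel_size_um %||% attr(stack, "pixel_size_um")
    frames <- list(unclass(stack))
  } else frames <- stack
  stopifnot(length(frames) >= 1L, all(vapply(frames, is.matrix, logical(1))))
  if (is.null(pixel_size_um)) stop("pixel_size_um calibration is required")
  desc <- paste0("ovquant\npixel_size_um=", format(pixel_size_um, digits = 17),
                 if (!is.null(frame_interval_min) && is.finite(frame_interval_min))
                   paste0("\nframe_interval_min=",
                          format(frame_interval_min, digits = 17)) else "",
                 "\n")
  desc_raw <- c(charToRaw(desc), as.raw(0))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  bps <- switch(format, float32 = 32L, uint16 = 16L, uint8 = 8L,
                stop("unsupported format: ", format))
  sfmt <- if (format == "float32") 3L else 1L
  bytes_px <- bps / 8L
  strip_len <- h * w * bytes_px

  con <- file(path, "wb")
  on.exit(close(con))
  wU32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wU16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  n <- length(frames)
  # layout: header (8) | description | pixel data pages | IFD chain
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  strip_offs <- data_off + (seq_len(n) - 1L) * strip_len
  ifd0 <- data_off + n * strip_len
  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con); wU16(42L); wU32(ifd0)
  writeBin(desc_raw, con)
  for (f in frames) {
    v <- as.vector(t(f))  # row-major
    if (format == "float32") writeBin(v, con, size = 4, endian = "little")
    else writeBin(as.integer(round(v)), con, size = bytes_px, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    wU16(tag); wU16(type); wU32(count)
    if (type == 3L) { wU16(value); wU16(0L) } else wU32(value)
  }
  for (i in seq_len(n)) {
    wU16(n_entries)
    entry(256L, 4L, 1L, w)                 # ImageWidth
    entry(257L, 4L, 1L, h)                 # ImageLength
    entry(258L, 3L, 1L, bps)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression = none
    entry(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    entry(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    entry(273L, 4L, 1L, strip_offs[i])     # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, h)                 # RowsPerStrip
    entry(279L, 4L, 1L, strip_len)         # StripByteCounts
    entry(339L, 3L, 1L, sfmt)              # SampleFormat
    wU32(if (i < n) ifd0 + i * ifd_size else 0L)  # next IFD
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into an image stack
#'
#' Supports uncompressed, single-sample, little- or big-endian baseline
#' TIFF with 8/16-bit unsigned or 32-bit float pixels. Calibration is
#' taken from an `ImageDescription` written by [write_tiff_stack()]; the
#' `pixel_size_um` / `frame_interval_min` arguments override or supply
#' it. A file with no calibration from either source is refused.
#'
#' @param path TIFF file.
#' @param pixel_size_um,frame_interval_min calibration overrides.
#' @return an [image_stack()] of matrices.
#' @export
read_tiff_stack <- function(path, pixel_size_um = NULL, frame_interval_min = NULL) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: too short")
  endian <- if (rawToChar(raw_all[1:2]) == "II") "little"
  else if (rawToChar(raw_all[1:2]) == "MM") "big"
  else stop("not a TIFF file: bad byte-order mark")
  rU <- function(off, size, n = 1L)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = FALSE)
  rU32 <- function(off, n = 1L) {  # unsigned 32-bit via double
    lo <- rU(off, 2, 2 * n)
    if (endian == "little") lo[seq(1, 2 * n, 2)] + 65536 * lo[seq(2, 2 * n, 2)]
    else lo[seq(2, 2 * n, 2)] + 65536 * lo[seq(1, 2 * n, 2)]
  }
  if (rU(2, 2) != 42L) stop("not a TIFF file: bad magic")
  ifd <- rU32(4)
  frames <- list()
  desc <- NULL
  while (ifd != 0) {
    nent <- rU(ifd, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- rU(off, 2); type <- rU(off + 2, 2); count <- rU32(off + 4)
      tsize <- c(1, 1, 2, 4, 8)[type]
      if (is.na(tsize)) next
      voff <- if (count * tsize <= 4) off + 8 else rU32(off + 8)
      val <- if (type == 2L) {
        rawToChar(raw_all[(voff + 1):(voff + count - 1)])
      } else if (type == 3L) rU(voff, 2, count)
      else if (type == 4L) rU32(voff, count)
      else if (type == 1L) rU(voff, 1, count)
      else NULL
      tags[[as.character(tag)]] <- val
    }
    need <- function(t, dflt = NULL) tags[[as.character(t)]] %||% dflt
    w <- need(256); h <- need(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
    if (need(277, 1L) != 1L) stop("multi-sample TIFF not supported")
    bps <- need(258, 1L)
    sfmt <- need(339, 1L)
    if (!is.null(need(270))) desc <- need(270)
    offs <- need(273); cnts <- need(279)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[(offs[s] + 1):(offs[s] + cnts[s])])
    px <- if (bps == 32L && sfmt == 3L) {
      readBin(buf, "double", n = w * h, size = 4, endian = endian)
    } else if (bps %in% c(8L, 16L) && sfmt == 1L) {
      readBin(buf, "integer", n = w * h, size = bps / 8, endian = endian,
              signed = FALSE)
    } else stop("unsupported TIFF pixel format: ", bps, "-bit sample format ", sfmt)
    frames[[length(frames) + 1L]] <- matrix(px, h, w, byrow = TRUE)
    ifd <- rU32(ifd + 2 + nent * 12)
  }
  if (!is.null(desc)) {
    for (line in strsplit(desc, "\n")[[1]]) {
      if (grepl("^pixel_size_um=", line) && is.null(pixel_size_um))
        pixel_size_um <- as.numeric(sub("^pixel_size_um=", "", line))
      if (grepl("^frame_interval_min=", line) && is.null(frame_interval_min))
        frame_interval_min <- as.numeric(sub("^frame_interval_min=", "", line))
    }
  }
  if (is.null(pixel_size_um))
    stop("missing calibration: no pixel_size_um in file or arguments")
  image_stack(frames, pixel_size_um,
              frame_interval_min %||% NA_real_)
}
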