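# Minimal baseline TIFF I/O: multi-page, uncompressed, 16-bit unsigned,
# single-sample grayscale, little-endian. Hand-rolled because no
# TIFF-capable R package is available in the target environment; covers
# exactly the dialect the renderer produces, and rejects anything else.

.tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
.tiff_u32 <- function(x) {
  # writeBin has no unsigned 32-bit type; values stay < 2^31 here
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.tiff_tag <- function(id, type, count, value) {
  val <- if (type == 3L) c(.tiff_u16(value), .tiff_u16(0)) else .tiff_u32(value)
  c(.tiff_u16(id), .tiff_u16(type), .tiff_u32(count), val)
}

#' Write a 16-bit grayscale multi-page TIFF
#'
#' One page per frame, uncompressed, little-endian, one strip per page.
#'
#' @param stack integer array `[height, width, frames]` (a `frame_stack`)
#'   or a single `[height, width]` matrix; values in `[0, 65535]`.
#' @param path output file.
#' @export
write_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  d <- dim(stack)
  if (length(d) != 3) stop("write_tiff: stack must be [height, width, frames]")
  if (min(stack) < 0 || max(stack) > 65535)
    stop("write_tiff: values out of 16-bit range")
  h <- d[1]; w <- d[2]; n <- d[3]
  strip_size <- w * h * 2L
  ifd_size <- 2L + 9L * 12L + 4L
  page_size <- strip_size + ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.tiff_u16(42L), con)
  writeBin(.tiff_u32(8L + strip_size), con)      # first IFD offset
  for (fi in seq_len(n)) {
    data_off <- 8L + (fi - 1L) * page_size
    ifd_off <- data_off + strip_size
    # pixel data, row-major
    px <- as.integer(t(stack[, , fi]))
    px[px > 32767L] <- px[px > 32767L] - 65536L  # writeBin wants signed
    writeBin(px, con, size = 2, endian = "little")
    ifd <- c(.tiff_u16(9L),
             .tiff_tag(256L, 3L, 1L, w),          # ImageWidth
             .tiff_tag(257L, 3L, 1L, h),          # ImageLength
             .tiff_tag(258L, 3L, 1L, 16L),        # BitsPerSample
             .tiff_tag(259L, 3L, 1L, 1L),         # Compression: none
             .tiff_tag(262L, 3L, 1L, 1L),         # Photometric: min-is-black
             .tiff_tag(273L, 4L, 1L, data_off),   # StripOffsets
             .tiff_tag(277L, 3L, 1L, 1L),         # SamplesPerPixel
             .tiff_tag(278L, 3L, 1L, h),          # RowsPerStrip
             .tiff_tag(279L, 4L, 1L, strip_size), # StripByteCounts
             .tiff_u32(if (fi < n) ifd_off + ifd_size + strip_size else 0L))
    writeBin(ifd, con)
  }
  invisible(path)
}

.tiff_read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
.tiff_read_u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

#' Read a 16-bit grayscale multi-page TIFF
#'
#' Supports the baseline dialect written by [write_tiff()] (uncompressed,
#' little-endian, 16-bit single-sample; arbitrary strip layout).
#'
#' @param path TIFF file.
#' @return integer array `[height, width, frames]` of class `frame_stack`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || .tiff_read_u16(raw, 2) != 42L)
    stop("read_tiff: not a little-endian TIFF")
  ifd_off <- .tiff_read_u32(raw, 4)
  frames <- list()
  while (ifd_off != 0) {
    n_tags <- .tiff_read_u16(raw, ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd_off + 2 + (i - 1) * 12
      id <- .tiff_read_u16(raw, base)
      type <- .tiff_read_u16(raw, base + 2)
      count <- .tiff_read_u32(raw, base + 4)
      width_b <- switch(as.character(type), "3" = 2L, "4" = 4L, NA_integer_)
      if (is.na(width_b)) { tags[[as.character(id)]] <- NULL; next }
      total <- width_b * count
      voff <- if (total <= 4) base + 8 else .tiff_read_u32(raw, base + 8)
      vals <- vapply(seq_len(count), function(j) {
        o <- voff + (j - 1) * width_b
        if (width_b == 2L) as.numeric(.tiff_read_u16(raw, o))
        else .tiff_read_u32(raw, o)
      }, numeric(1))
      tags[[as.character(id)]] <- vals
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("read_tiff: missing tag ", id)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    if (!identical(need(258L, 1), 16)) stop("read_tiff: only 16-bit supported")
    if (!identical(need(259L, 1), 1)) stop("read_tiff: compressed TIFF unsupported")
    if (!identical(need(277L, 1), 1)) stop("read_tiff: multi-sample unsupported")
    offs <- need(273L); cnts <- need(279L)
    px <- integer(0)
    for (s in seq_along(offs)) {
      seg <- raw[(offs[s] + 1):(offs[s] + cnts[s])]
      v <- readBin(seg, "integer", n = cnts[s] / 2, size = 2,
                   signed = FALSE, endian = "little")
      px <- c(px, v)
    }
    if (length(px) != w * h) stop("read_tiff: strip size mismatch")
    frames[[length(frames) + 1]] <- matrix(px, nrow = h, ncol = w,
                                           byrow = TRUE)
    ifd_off <- .tiff_read_u32(raw, ifd_off + 2 + n_tags * 12)
  }
  stack <- array(0L, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                             length(frames)))
  for (i in seq_along(frames)) stack[, , i] <- frames[[i]]
  class(stack) <- "frame_stack"
  stack
}
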