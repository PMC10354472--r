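# Thermal stacks: multipage TIFF of 16-bit raw sensor counts plus a JSON
# sidecar carrying per-frame timestamps and probe pixel annotations.
#
# The codec below implements the minimal baseline-TIFF subset this package
# needs (little-endian, uncompressed, single-strip, 16-bit grayscale,
# multipage). It exists because the deployment environment has no R TIFF
# bindings; it is not a general TIFF reader.

#' Construct a thermal stack
#'
#' @param frames list of numeric matrices of raw sensor counts, all the same
#'   dimension; matrix rows are image rows (y down), columns are x.
#' @param timestamps_s numeric vector, one per frame, seconds from video
#'   start.
#' @param probes data.frame with `probe_id`, `x_px`, `y_px` (0-based pixel
#'   annotation of each in-nest probe).
#' @return An object of class `thermal_stack`.
#' @export
thermal_stack <- function(frames, timestamps_s, probes) {
  stopifnot(is.list(frames), length(frames) == length(timestamps_s))
  dims <- unique(lapply(frames, dim))
  if (length(dims) > 1L) stop("all frames must share one dimension")
  stopifnot(all(c("probe_id", "x_px", "y_px") %in% names(probes)))
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  if (any(probes$x_px < 0 | probes$x_px > w - 1 |
          probes$y_px < 0 | probes$y_px > h - 1))
    stop("probe annotation outside frame")
  structure(list(frames = frames, timestamps_s = as.numeric(timestamps_s),
                 probes = probes, width = w, height = h),
            class = "thermal_stack")
}

#' @export
print.thermal_stack <- function(x, ...) {
  cat(sprintf("<thermal_stack: %d frames of %dx%d, %d probes>\n",
              length(x$frames), x$width, x$height, nrow(x$probes)))
  invisible(x)
}

tiff_tag <- function(id, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (left-justified LE)
  con <- raw()
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L)
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    else writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write a thermal stack as multipage TIFF + JSON sidecar
#'
#' Counts are rounded to the nearest integer and clamped to `[0, 65535]`.
#' The sidecar (`<path>.json`) carries timestamps and probe annotations.
#'
#' @param stack a `thermal_stack`.
#' @param path output `.tif` path.
#' @export
write_thermal_stack <- function(stack, path) {
  w <- stack$width; h <- stack$height
  n <- length(stack$frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  header_len <- 8L
  strip_bytes <- 2L * w * h
  ifd_len <- 2L + 9L * 12L + 4L
  page_len <- strip_bytes + ifd_len
  first_ifd <- header_len + strip_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (i in seq_len(n)) {
    m <- stack$frames[[i]]
    counts <- pmin(pmax(round(m), 0), 65535)
    # TIFF is row-major: transpose so writeBin emits row after row
    v <- as.integer(t(counts))
    # writeBin has no uint16: emit via raw bytes
    lo <- as.raw(v %% 256L); hi <- as.raw(v %/% 256L)
    bytes <- as.vector(rbind(lo, hi))
    writeBin(bytes, con)
    strip_offset <- header_len + (i - 1L) * page_len
    next_ifd <- if (i < n) strip_offset + page_len + strip_bytes else 0L
    ifd <- c(
      writeBin(9L, raw(), size = 2, endian = "little"),
      tiff_tag(256, 3, 1, w),            # ImageWidth
      tiff_tag(257, 3, 1, h),            # ImageLength
      tiff_tag(258, 3, 1, 16),           # BitsPerSample
      tiff_tag(259, 3, 1, 1),            # Compression: none
      tiff_tag(262, 3, 1, 1),            # Photometric: BlackIsZero
      tiff_tag(273, 4, 1, strip_offset), # StripOffsets
      tiff_tag(278, 3, 1, h),            # RowsPerStrip
      tiff_tag(279, 4, 1, strip_bytes),  # StripByteCounts
      tiff_tag(339, 3, 1, 1),            # SampleFormat: unsigned int
      writeBin(as.integer(next_ifd), raw(), size = 4, endian = "little"))
    writeBin(ifd, con)
  }
  jsonlite::write_json(
    list(timestamps_s = stack$timestamps_s,
         probes = stack$probes,
         width = w, height = h),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

read_u <- function(bytes, at, size) {
  b <- as.integer(bytes[at + seq_len(size) - 1L])
  sum(b * 256^(seq_len(size) - 1L))
}

#' Read a thermal stack written by [write_thermal_stack()]
#'
#' @param path `.tif` path; expects the `<path>.json` sidecar next to it.
#' @return A `thermal_stack` with integer count matrices.
#' @export
read_thermal_stack <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(bytes[1:2]) != "II" || read_u(bytes, 3L, 2L) != 42L)
    stop("not a little-endian TIFF: ", path)
  ifd_offset <- read_u(bytes, 5L, 4L)
  frames <- list()
  while (ifd_offset != 0L) {
    at <- ifd_offset + 1L
    n_tags <- read_u(bytes, at, 2L)
    tags <- list()
    for (k in seq_len(n_tags)) {
      base <- at + 2L + (k - 1L) * 12L
      id <- read_u(bytes, base, 2L)
      type <- read_u(bytes, base + 2L, 2L)
      val <- read_u(bytes, base + 8L, if (type == 3L) 2L else 4L)
      tags[[as.character(id)]] <- val
    }
    if (is.null(tags[["259"]]) || tags[["259"]] != 1L)
      stop("unsupported TIFF compression")
    if (is.null(tags[["258"]]) || tags[["258"]] != 16L)
      stop("only 16-bit samples supported")
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]
    raw_px <- bytes[off + seq_len(2L * w * h)]
    lo <- as.integer(raw_px[c(TRUE, FALSE)])
    hi <- as.integer(raw_px[c(FALSE, TRUE)])
    frames[[length(frames) + 1L]] <- matrix(lo + 256L * hi, nrow = h,
                                            ncol = w, byrow = TRUE)
    ifd_offset <- read_u(bytes, at + 2L + n_tags * 12L, 4L)
  }
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  thermal_stack(frames, side$timestamps_s, as.data.frame(side$probes))
}
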