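# Minimal baseline TIFF codec: uncompressed 16-bit grayscale, single strip.
# Fallback format for detectors that cannot export DICOM. Pixel spacing is
# stored in X/YResolution (pixels per cm); files written without it need a
# spacing override in the device config on read.

#' Write a 16-bit grayscale TIFF
#'
#' @param image a [phantom_image]
#' @param path output path
#' @param with_resolution store the pixel spacing in the resolution tags
#'   (disable to emulate vendors that omit it)
#' @export
write_tiff16 <- function(image, path, with_resolution = TRUE) {
  px <- image$pixels
  if (any(px < 0 | px > 65535) || any(px != round(px)))
    stop("write_tiff16: pixels must be integers in [0, 65535]")
  nr <- nrow(px); nc <- ncol(px)
  data_bytes <- u16le_bytes(as.integer(t(px)))

  entry <- function(tag, type, count, value) c(u16le_bytes(tag), u16le_bytes(type),
                                               u32le_bytes(count), value)
  short_val <- function(x) c(u16le_bytes(x), as.raw(c(0, 0)))
  long_val <- u32le_bytes

  n_entries <- if (with_resolution) 12L else 9L
  # layout: 8-byte header | pixel data | IFD | rational values
  ifd_offset <- 8 + length(data_bytes)
  rat_offset <- ifd_offset + 2 + n_entries * 12 + 4
  entries <- list(
    entry(256, 3, 1, short_val(nc)),                 # ImageWidth
    entry(257, 3, 1, short_val(nr)),                 # ImageLength
    entry(258, 3, 1, short_val(16)),                 # BitsPerSample
    entry(259, 3, 1, short_val(1)),                  # Compression: none
    entry(262, 3, 1, short_val(1)),                  # Photometric: BlackIsZero
    entry(273, 4, 1, long_val(8)),                   # StripOffsets
    entry(277, 3, 1, short_val(1)),                  # SamplesPerPixel
    entry(278, 3, 1, short_val(nr)),                 # RowsPerStrip
    entry(279, 4, 1, long_val(length(data_bytes))))  # StripByteCounts
  if (with_resolution) {
    entries <- c(entries, list(
      entry(282, 5, 1, long_val(rat_offset)),        # XResolution
      entry(283, 5, 1, long_val(rat_offset + 8)),    # YResolution
      entry(296, 3, 1, short_val(3))))               # ResolutionUnit: cm
  }
  # sort by tag id as the spec requires
  tags <- vapply(entries, function(e) as.integer(e[1]) + 256L * as.integer(e[2]), integer(1))
  entries <- entries[order(tags)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le_bytes(42), u32le_bytes(ifd_offset)), con)
  writeBin(data_bytes, con)
  writeBin(u16le_bytes(n_entries), con)
  writeBin(do.call(c, entries), con)
  writeBin(u32le_bytes(0), con)  # no next IFD
  if (with_resolution) {
    # pixels per cm as a rational with denominator 10^6
    for (p in image$pixel_spacing_mm[c(2, 1)]) {
      ppcm <- 10 / p
      writeBin(c(u32le_bytes(round(ppcm * 1e6)), u32le_bytes(1e6)), con)
    }
  }
  invisible(path)
}

#' Read a 16-bit grayscale TIFF
#'
#' @param path input file
#' @return list with `pixels` (integer matrix) and `pixel_spacing_mm`
#'   (`c(row, col)` in mm, or `NULL` when the file has no resolution tags)
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  byte_order <- rawToChar(raw[1:2])
  if (!byte_order %in% c("II", "MM")) stop("not a TIFF file: ", path)
  endian <- if (byte_order == "II") "little" else "big"
  rd <- function(at, n, size) readBin(raw[at:(at + n * size - 1L)], "integer",
                                      n = n, size = size, signed = FALSE,
                                      endian = endian)
  if (rd(3L, 1L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- readBin(raw[5:8], "integer", n = 1, size = 4, endian = endian)
  n_entries <- rd(ifd + 1L, 1L, 2L)
  tags <- list()
  for (k in seq_len(n_entries)) {
    at <- ifd + 3L + (k - 1L) * 12L
    tag <- rd(at, 1L, 2L); type <- rd(at + 2L, 1L, 2L)
    count <- rd(at + 4L, 1L, 4L)
    val <- if (type == 3L) rd(at + 8L, 1L, 2L) else rd(at + 8L, 1L, 4L)
    tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
  }
  g <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) default else t$value
  }
  nc <- g(256); nr <- g(257)
  if (is.null(nc) || is.null(nr)) stop("TIFF missing image dimensions")
  if (g(258, 1) != 16) stop("only 16-bit TIFF images are supported")
  if (g(259, 1) != 1) stop("only uncompressed TIFF images are supported")
  offset <- g(273); count_bytes <- g(279, nr * nc * 2)
  if (is.null(offset)) stop("TIFF missing strip offset")
  v <- readBin(raw[(offset + 1L):(offset + nr * nc * 2L)], "integer",
               n = nr * nc, size = 2L, signed = FALSE, endian = endian)
  pixels <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  spacing <- NULL
  if (!is.null(tags[["282"]]) && !is.null(tags[["296"]]) && g(296) == 3) {
    rd_rational <- function(off) {
      num <- rd(off + 1L, 1L, 4L); den <- rd(off + 5L, 1L, 4L)
      num / den
    }
    xres <- rd_rational(g(282)); yres <- rd_rational(g(283, g(282)))
    spacing <- c(10 / yres, 10 / xres)  # cm resolution -> mm spacing
  }
  list(pixels = pixels, pixel_spacing_mm = spacing)
}
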