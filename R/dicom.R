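# Minimal DICOM codec (part-10, explicit VR little endian).
#
# No DICOM package exists in the deployment environment, so the subset this
# tool needs is implemented here: uncompressed 16-bit monochrome images plus
# the acquisition tags tracked by the QC programme. The reader also accepts
# implicit VR little endian and preserves unknown tags as raw bytes; it
# never invents metadata (an unmapped/absent tag reads back as NA).

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

# tag -> (field, VR) used when writing; the read-side default tag map.
DICOM_TAG_MAP <- list(
  kvp              = list(tag = c(0x0018, 0x0060), vr = "DS"),
  tube_load_uas    = list(tag = c(0x0018, 0x1153), vr = "IS"),
  exposure_mas     = list(tag = c(0x0018, 0x1152), vr = "IS"),
  exposure_index   = list(tag = c(0x0018, 0x1411), vr = "DS"),
  organ_dose       = list(tag = c(0x0040, 0x0316), vr = "DS"),
  entrance_dose    = list(tag = c(0x0040, 0x8302), vr = "DS"),
  anode_filter     = list(tag = c(0x0018, 0x1191), vr = "CS"),
  detector_id      = list(tag = c(0x0018, 0x700A), vr = "SH"),
  station_name     = list(tag = c(0x0008, 0x1010), vr = "SH"),
  acq_datetime     = list(tag = c(0x0008, 0x002A), vr = "DT"))

u16le_bytes <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}
u32le_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dicom_element <- function(group, element, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2L == 1L) {  # even-length padding
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad); n <- n + 1L
  }
  head <- c(u16le_bytes(group), u16le_bytes(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), u32le_bytes(n), value_raw)
  } else {
    if (n > 65534) stop("DICOM element too long for short VR ", vr)
    c(head, u16le_bytes(n), value_raw)
  }
}

dicom_str_element <- function(group, element, vr, s)
  dicom_element(group, element, vr, charToRaw(as.character(s)))

#' Write a phantom image as a DICOM file
#'
#' Explicit VR little endian, monochrome (MONOCHROME2), 16-bit unsigned.
#' Pixel values must already be integers in \[0, 65535\].
#'
#' @param image a [phantom_image]
#' @param path output path
#' @export
write_dicom <- function(image, path) {
  px <- image$pixels
  if (any(px < 0 | px > 65535) || any(px != round(px)))
    stop("write_dicom: pixels must be integers in [0, 65535]")
  md <- image$metadata
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture
  sop_inst <- "1.2.826.0.1.3680043.9590.1"  # fixed: deterministic output

  ds <- list()
  add <- function(el) ds[[length(ds) + 1L]] <<- el
  add(dicom_str_element(0x0008, 0x0016, "UI", sop_class))
  add(dicom_str_element(0x0008, 0x0018, "UI", sop_inst))
  if (!is.na(md$acquisition_datetime))
    add(dicom_str_element(0x0008, 0x002A, "DT",
        format(md$acquisition_datetime, "%Y%m%d%H%M%S", tz = "UTC")))
  add(dicom_str_element(0x0008, 0x0060, "CS",
      if (image$modality == "mammography") "MG" else "DX"))
  add(dicom_str_element(0x0008, 0x0068, "CS",
      switch(image$presentation_state,
             for_processing = "FOR PROCESSING",
             for_presentation = "FOR PRESENTATION",
             "FOR PROCESSING")))
  if (!is.na(md$station_name))
    add(dicom_str_element(0x0008, 0x1010, "SH", md$station_name))
  if (!is.na(md$kvp))
    add(dicom_str_element(0x0018, 0x0060, "DS", format(md$kvp, digits = 10)))
  if (!is.na(md$tube_load_mas)) {
    add(dicom_str_element(0x0018, 0x1152, "IS", round(md$tube_load_mas)))
    add(dicom_str_element(0x0018, 0x1153, "IS", round(md$tube_load_mas * 1000)))
  }
  add(dicom_str_element(0x0018, 0x1164, "DS",
      paste(format(image$pixel_spacing_mm, digits = 10), collapse = "\\")))
  if (!is.na(md$anode_filter))
    add(dicom_str_element(0x0018, 0x1191, "CS", md$anode_filter))
  if (!is.na(md$exposure_index))
    add(dicom_str_element(0x0018, 0x1411, "DS", format(md$exposure_index, digits = 10)))
  if (!is.na(md$detector_id))
    add(dicom_str_element(0x0018, 0x700A, "SH", md$detector_id))
  add(dicom_element(0x0028, 0x0002, "US", u16le_bytes(1L)))
  add(dicom_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"))
  add(dicom_element(0x0028, 0x0010, "US", u16le_bytes(nrow(px))))
  add(dicom_element(0x0028, 0x0011, "US", u16le_bytes(ncol(px))))
  add(dicom_str_element(0x0028, 0x0030, "DS",
      paste(format(image$pixel_spacing_mm, digits = 10), collapse = "\\")))
  add(dicom_element(0x0028, 0x0100, "US", u16le_bytes(16L)))
  add(dicom_element(0x0028, 0x0101, "US", u16le_bytes(16L)))
  add(dicom_element(0x0028, 0x0102, "US", u16le_bytes(15L)))
  add(dicom_element(0x0028, 0x0103, "US", u16le_bytes(0L)))
  if (!is.na(md$organ_dose))
    add(dicom_str_element(0x0040, 0x0316, "DS", format(md$organ_dose, digits = 10)))
  if (!is.na(md$entrance_dose))
    add(dicom_str_element(0x0040, 0x8302, "DS", format(md$entrance_dose, digits = 10)))
  # pixel data, row-major
  add(dicom_element(0x7FE0, 0x0010, "OW", u16le_bytes(as.integer(t(px)))))

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_str_element(0x0002, 0x0002, "UI", sop_class),
    dicom_str_element(0x0002, 0x0003, "UI", sop_inst),
    dicom_str_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  meta <- c(dicom_element(0x0002, 0x0000, "UL", u32le_bytes(length(meta))), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(do.call(c, ds), con)
  invisible(path)
}

# Parse a DICOM file into a list keyed "gggg,eeee" (lowercase hex) with
# decoded values for known VRs; pixel-related tags decoded specially.
read_dicom_elements <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 160 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  ts <- TS_EXPLICIT_LE
  elements <- list()
  rd_u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  rd_u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  in_meta <- TRUE
  while (pos + 7L <= length(raw)) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", ts)
    }
    explicit <- in_meta || ts == TS_EXPLICIT_LE
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- rd_u32(pos + 8L); hdr <- 12L
      } else {
        len <- rd_u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- rd_u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    val_at <- pos + hdr
    if (val_at + len - 1L > length(raw)) stop("truncated DICOM element at byte ", pos)
    value <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    elements[[key]] <- list(vr = vr, raw = value)
    pos <- val_at + len
    if (group == 0x0002 && element == 0x0010) ts <- dicom_decode_string(value)
  }
  elements
}

dicom_decode_string <- function(value_raw) {
  s <- rawToChar(value_raw[value_raw != as.raw(0)])
  trimws(s)
}

dicom_get_string <- function(elements, key) {
  el <- elements[[tolower(key)]]
  if (is.null(el)) return(NA_character_)
  dicom_decode_string(el$raw)
}

dicom_get_numeric <- function(elements, key) {
  s <- dicom_get_string(elements, key)
  if (is.na(s) || s == "") return(NA_real_)
  suppressWarnings(as.numeric(strsplit(s, "\\\\")[[1]][1]))
}

dicom_pixel_matrix <- function(elements) {
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (any(!need %in% names(elements)))
    stop("DICOM file has no usable pixel data")
  rd_us <- function(key) {
    v <- elements[[key]]$raw
    as.integer(v[1]) + 256L * as.integer(v[2])
  }
  rows <- rd_us("0028,0010"); cols <- rd_us("0028,0011")
  bits <- if ("0028,0100" %in% names(elements)) rd_us("0028,0100") else 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  pd <- elements[["7fe0,0010"]]$raw
  if (length(pd) < 2 * rows * cols) stop("DICOM pixel data shorter than Rows x Columns")
  v <- readBin(pd, "integer", n = rows * cols, size = 2L,
               signed = FALSE, endian = "little")
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}
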