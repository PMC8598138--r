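# Image + metadata input, acquisition-consistency validation, and the CSV
# record format exchanged with the remote QC center.

#' Read a phantom image from DICOM or TIFF
#'
#' Vendor-specific metadata tags are resolved through the optional
#' `tag_map` entry of `device_config` (field name -> `"gggg,eeee"` DICOM tag
#' string); unmapped or absent tags read back as `NA`, never as a default
#' number. Images with inverted polarity (MONOCHROME1) are flipped so that
#' higher value = more signal.
#'
#' @param path DICOM or TIFF file
#' @param device_config optional list; recognized entries:
#'   `modality`, `pixel_spacing_mm` (override/fallback), `tag_map`
#' @return a [phantom_image]; a warning is emitted when the presentation
#'   intent is not "FOR PROCESSING" (processed images should be avoided)
#' @export
read_phantom_image <- function(path, device_config = list()) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  magic <- readBin(path, "raw", n = 132)
  is_dicom <- length(magic) >= 132 && rawToChar(magic[129:132]) == "DICM"
  is_tiff <- length(magic) >= 4 && rawToChar(magic[1:2]) %in% c("II", "MM")
  if (is_dicom) read_phantom_dicom(path, device_config)
  else if (is_tiff) read_phantom_tiff(path, device_config)
  else stop("unrecognized image format (not DICOM part-10 or TIFF): ", path)
}

read_phantom_dicom <- function(path, device_config) {
  el <- read_dicom_elements(path)
  pixels <- dicom_pixel_matrix(el)

  photometric <- dicom_get_string(el, "0028,0004")
  inverted <- identical(photometric, "MONOCHROME1")
  if (inverted) pixels <- 65535 - pixels

  spacing <- device_config$pixel_spacing_mm
  if (is.null(spacing)) {
    s <- dicom_get_string(el, "0018,1164")
    if (is.na(s)) s <- dicom_get_string(el, "0028,0030")
    if (!is.na(s)) spacing <- as.numeric(strsplit(s, "\\\\")[[1]])
  }
  if (is.null(spacing) || any(!is.finite(spacing)))
    stop("no pixel spacing in the DICOM header and no device_config ",
         "override; frequency metrics would be meaningless")

  intent <- dicom_get_string(el, "0008,0068")
  state <- if (is.na(intent)) {
    warning("presentation intent absent from header; assuming 'unknown'")
    "unknown"
  } else if (grepl("PROCESSING", intent)) "for_processing"
  else if (grepl("PRESENTATION", intent)) {
    warning("image is 'FOR PRESENTATION' (processed); metrics may be biased")
    "for_presentation"
  } else "unknown"

  dicom_modality <- dicom_get_string(el, "0008,0060")
  modality <- device_config$modality %||%
    (if (identical(dicom_modality, "MG")) "mammography" else "radiography")

  tm <- resolve_tag_map(device_config$tag_map)
  mas <- dicom_get_numeric(el, tm$tube_load_uas)
  if (!is.na(mas)) mas <- mas / 1000 else mas <- dicom_get_numeric(el, tm$exposure_mas)
  dt_s <- dicom_get_string(el, tm$acq_datetime)
  acq_dt <- if (!is.na(dt_s))
    as.POSIXct(dt_s, format = "%Y%m%d%H%M%S", tz = "UTC") else as.POSIXct(NA)

  md <- acquisition_metadata(
    kvp = dicom_get_numeric(el, tm$kvp),
    tube_load_mas = mas,
    exposure_index = dicom_get_numeric(el, tm$exposure_index),
    organ_dose = dicom_get_numeric(el, tm$organ_dose),
    entrance_dose = dicom_get_numeric(el, tm$entrance_dose),
    anode_filter = dicom_get_string(el, tm$anode_filter),
    detector_id = dicom_get_string(el, tm$detector_id),
    station_name = dicom_get_string(el, tm$station_name),
    acquisition_datetime = acq_dt)

  img <- new_phantom_image(pixels, rep(spacing, length.out = 2), modality,
                           state, md)
  if (inverted) attr(img, "provenance") <- "polarity flipped from MONOCHROME1"
  img
}

resolve_tag_map <- function(tag_map) {
  tm <- lapply(DICOM_TAG_MAP, function(e)
    sprintf("%04x,%04x", e$tag[1], e$tag[2]))
  for (nm in names(tag_map)) tm[[nm]] <- tolower(tag_map[[nm]])
  tm
}

read_phantom_tiff <- function(path, device_config) {
  t <- read_tiff16(path)
  spacing <- device_config$pixel_spacing_mm %||% t$pixel_spacing_mm
  if (is.null(spacing))
    stop("TIFF has no resolution tags and no device_config pixel spacing ",
         "override; frequency metrics would be meaningless")
  warning("TIFF input carries no presentation intent; assuming 'unknown'")
  new_phantom_image(t$pixels, rep(spacing, length.out = 2),
                    device_config$modality %||% "radiography",
                    "unknown", acquisition_metadata())
}

#' Check an image against the acquisition protocol
#'
#' Pure reporting: returns human-readable violations, never raises.
#'
#' @param image a [phantom_image]
#' @param protocol list with any of `expected_kvp`, `kvp_tolerance`
#'   (default 0.5 kV), `modality`, `detector_id`
#' @return character vector of violations (empty when compliant)
#' @export
validate_acquisition <- function(image, protocol = list()) {
  v <- character()
  md <- image$metadata
  if (!is.null(protocol$expected_kvp)) {
    tol <- protocol$kvp_tolerance %||% 0.5
    if (is.na(md$kvp)) {
      v <- c(v, "kVp not recorded in the image header")
    } else if (abs(md$kvp - protocol$expected_kvp) > tol) {
      v <- c(v, sprintf("kVp mismatch: header %.4g, protocol expects %.4g",
                        md$kvp, protocol$expected_kvp))
    }
  }
  if (!is.null(protocol$modality) && image$modality != protocol$modality)
    v <- c(v, sprintf("modality mismatch: image is %s, protocol expects %s",
                      image$modality, protocol$modality))
  if (!is.null(protocol$detector_id)) {
    if (is.na(md$detector_id)) {
      v <- c(v, "detector ID not recorded in the image header")
    } else if (md$detector_id != protocol$detector_id) {
      v <- c(v, sprintf("wrong detector: header '%s', protocol expects '%s'",
                        md$detector_id, protocol$detector_id))
    }
  }
  if (image$presentation_state == "for_presentation")
    v <- c(v, "image is processed ('for presentation'); unprocessed images are required")
  v
}

# ---------------------------------------------------------------------------
# QcRecord: one session's metric vector, exchanged as CSV.

QC_CSV_COLUMNS <- c("device_key", "acquisition_datetime", "kvp", "mas",
                    "exposure_index", "organ_dose", "entrance_dose",
                    "snr", "sdnr",
                    "mtf50_h", "mtf20_h", "mtf10_h",
                    "mtf50_v", "mtf20_v", "mtf10_v",
                    "dprime_small", "dprime_large",
                    "uniformity_flag", "software_version")

QC_NUMERIC_COLUMNS <- setdiff(QC_CSV_COLUMNS,
                              c("device_key", "acquisition_datetime",
                                "uniformity_flag", "software_version"))

#' Construct a QC record
#'
#' Missing values are `NA` (written as empty CSV cells), never zero.
#' @param device_key device identifier
#' @param acquisition_datetime `POSIXct`
#' @param ... any of the metric/header fields in the fixed column set:
#'   kvp, mas, exposure_index, organ_dose, entrance_dose, snr, sdnr,
#'   mtf50_h/mtf20_h/mtf10_h, mtf50_v/mtf20_v/mtf10_v (cycles/mm),
#'   dprime_small, dprime_large, uniformity_flag, software_version
#' @export
qc_record <- function(device_key, acquisition_datetime = as.POSIXct(NA), ...) {
  extra <- list(...)
  bad <- setdiff(names(extra), QC_CSV_COLUMNS)
  if (length(bad)) stop("unknown qc_record fields: ", paste(bad, collapse = ", "))
  rec <- stats::setNames(as.list(rep(NA_real_, length(QC_NUMERIC_COLUMNS))),
                         QC_NUMERIC_COLUMNS)
  rec$device_key <- as.character(device_key)
  rec$acquisition_datetime <- acquisition_datetime
  rec$uniformity_flag <- NA
  rec$software_version <- as.character(utils::packageVersion("phantomqc"))
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  for (nm in QC_NUMERIC_COLUMNS) {
    if (!is.na(rec[[nm]]) && !is.finite(rec[[nm]]))
      stop("qc_record field ", nm, " must be finite or NA")
    rec[[nm]] <- as.numeric(rec[[nm]])
  }
  structure(rec[QC_CSV_COLUMNS], class = "qc_record")
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
fmt_datetime <- function(x) ifelse(is.na(x), "",
                                   format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))

#' Write QC records to CSV
#'
#' Fixed, documented header; comma separator, "." decimal, ISO-8601 UTC
#' datetimes, empty cell = absent. `read_qc_csv(write_qc_csv(x)) == x`.
#'
#' @param records list of [qc_record()]s (may be empty)
#' @param path output file
#' @export
write_qc_csv <- function(records, path) {
  rows <- vapply(records, function(r) {
    stopifnot(inherits(r, "qc_record"))
    cells <- vapply(QC_CSV_COLUMNS, function(nm) {
      v <- r[[nm]]
      if (nm == "acquisition_datetime") fmt_datetime(v)
      else if (nm %in% QC_NUMERIC_COLUMNS) fmt_num(v)
      else if (nm == "uniformity_flag") {
        if (is.na(v)) "" else if (isTRUE(v)) "TRUE" else "FALSE"
      } else if (is.na(v)) "" else as.character(v)
    }, character(1))
    paste(cells, collapse = ",")
  }, character(1))
  writeLines(c(paste(QC_CSV_COLUMNS, collapse = ","), rows), path)
  invisible(path)
}

#' Read QC records from CSV
#'
#' @param path CSV written by [write_qc_csv()]
#' @return list of [qc_record()]s
#' @export
read_qc_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty QC CSV: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, QC_CSV_COLUMNS))
    stop("QC CSV header does not match the documented column set: ", path)
  out <- vector("list", length(lines) - 1L)
  for (i in seq_along(out)) {
    cells <- strsplit(paste0(lines[i + 1L], " "), ",", fixed = TRUE)[[1]]
    cells[length(cells)] <- trimws(cells[length(cells)])
    if (length(cells) != length(QC_CSV_COLUMNS))
      stop("malformed QC CSV row ", i + 1L, " in ", path,
           ": expected ", length(QC_CSV_COLUMNS), " fields, got ", length(cells))
    rec <- stats::setNames(as.list(cells), QC_CSV_COLUMNS)
    args <- list(device_key = rec$device_key,
                 acquisition_datetime = if (rec$acquisition_datetime == "")
                   as.POSIXct(NA)
                 else as.POSIXct(rec$acquisition_datetime,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    for (nm in QC_NUMERIC_COLUMNS) {
      if (rec[[nm]] != "") {
        val <- suppressWarnings(as.numeric(rec[[nm]]))
        if (is.na(val))
          stop("malformed QC CSV row ", i + 1L, ": field ", nm,
               " is not numeric ('", rec[[nm]], "')")
        args[[nm]] <- val
      }
    }
    if (rec$uniformity_flag != "")
      args$uniformity_flag <- identical(rec$uniformity_flag, "TRUE")
    if (rec$software_version != "")
      args$software_version <- rec$software_version
    out[[i]] <- do.call(qc_record, args)
  }
  out
}

#' Convert QC records to a data frame (one row per record)
#' @param records list of [qc_record()]s
#' @export
qc_records_to_df <- function(records) {
  if (length(records) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(QC_CSV_COLUMNS)),
                                        QC_CSV_COLUMNS))
    return(df)
  }
  do.call(rbind, lapply(records, function(r) {
    r <- unclass(r)
    r$acquisition_datetime <- fmt_datetime(r$acquisition_datetime)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}
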