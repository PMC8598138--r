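# DICOM/TIFF codecs, metadata rules, QC record CSV exchange.

make_test_image <- function(seed = 1, n = 48, state = "for_processing") {
  px <- with(list(), {
    set.seed(seed)
    matrix(sample.int(60000, n * n, replace = TRUE), n, n)
  })
  new_phantom_image(px, c(0.14, 0.14), "radiography", state,
                    acquisition_metadata(
                      kvp = 81.5, tube_load_mas = 10, exposure_index = 412,
                      organ_dose = 0.9, entrance_dose = 1.8,
                      anode_filter = "W/Cu", detector_id = "DET-7",
                      station_name = "ROOM2",
                      acquisition_datetime = as.POSIXct("2021-03-04 10:11:12",
                                                        tz = "UTC")))
}

test_that("DICOM write/read round-trips pixels and metadata", {
  img <- make_test_image()
  f <- tempfile(fileext = ".dcm")
  write_dicom(img, f)
  back <- read_phantom_image(f)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$pixel_spacing_mm, img$pixel_spacing_mm)
  expect_equal(back$metadata$kvp, 81.5)
  expect_equal(back$metadata$tube_load_mas, 10)
  expect_equal(back$metadata$exposure_index, 412)
  expect_equal(back$metadata$organ_dose, 0.9)
  expect_equal(back$metadata$entrance_dose, 1.8)
  expect_identical(back$metadata$detector_id, "DET-7")
  expect_equal(back$metadata$acquisition_datetime,
               img$metadata$acquisition_datetime)
  expect_identical(back$presentation_state, "for_processing")
  expect_identical(back$modality, "radiography")
})

test_that("processed images are flagged with a warning on read", {
  img <- make_test_image(state = "for_presentation")
  f <- tempfile(fileext = ".dcm")
  write_dicom(img, f)
  expect_warning(back <- read_phantom_image(f), "PRESENTATION")
  expect_identical(back$presentation_state, "for_presentation")
  expect_true(any(grepl("processed", validate_acquisition(back))))
})

test_that("MONOCHROME1 polarity is flipped to higher-value-is-more-signal", {
  img <- make_test_image()
  f <- tempfile(fileext = ".dcm")
  write_dicom(img, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  i <- grepRaw("MONOCHROME2", raw)
  raw[i + 10L] <- charToRaw("1")
  f2 <- tempfile(fileext = ".dcm")
  writeBin(raw, f2)
  back <- read_phantom_image(f2)
  expect_equal(back$pixels, 65535 - img$pixels, ignore_attr = TRUE)
  expect_match(attr(back, "provenance"), "polarity")
})

test_that("reader never invents metadata: absent tags stay NA", {
  img <- make_test_image()
  img$metadata <- acquisition_metadata()   # everything absent
  f <- tempfile(fileext = ".dcm")
  write_dicom(img, f)
  back <- read_phantom_image(f)
  expect_true(is.na(back$metadata$kvp))
  expect_true(is.na(back$metadata$exposure_index))
  expect_true(is.na(back$metadata$organ_dose))
  expect_true(is.na(back$metadata$detector_id))
})

test_that("vendor tag mapping redirects metadata lookup", {
  img <- make_test_image()
  f <- tempfile(fileext = ".dcm")
  write_dicom(img, f)
  # map exposure_index to a tag that is absent -> NA, not the default tag
  back <- read_phantom_image(f, list(tag_map = list(exposure_index = "0019,1000")))
  expect_true(is.na(back$metadata$exposure_index))
  # and to the kVp tag -> reads that number
  back2 <- read_phantom_image(f, list(tag_map = list(exposure_index = "0018,0060")))
  expect_equal(back2$metadata$exposure_index, 81.5)
})

test_that("TIFF round-trip, spacing fallback and config precedence", {
  img <- make_test_image()
  f <- tempfile(fileext = ".tif")
  write_tiff16(img, f)
  suppressWarnings(back <- read_phantom_image(f))
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$pixel_spacing_mm, img$pixel_spacing_mm, tolerance = 1e-6)

  f2 <- tempfile(fileext = ".tif")
  write_tiff16(img, f2, with_resolution = FALSE)
  expect_error(suppressWarnings(read_phantom_image(f2)), "spacing")
  suppressWarnings(back2 <- read_phantom_image(f2, list(pixel_spacing_mm = 0.1)))
  expect_equal(back2$pixel_spacing_mm, c(0.1, 0.1))
  expect_identical(back2$presentation_state, "unknown")
})

test_that("unreadable or missing files raise I/O errors", {
  expect_error(read_phantom_image(tempfile()), "cannot read")
  f <- tempfile()
  writeLines("not an image", f)
  expect_error(read_phantom_image(f), "unrecognized")
})

test_that("acquisition validation reports kVp, detector and modality issues", {
  img <- make_test_image()
  expect_length(validate_acquisition(img, list(expected_kvp = 81.5)), 0)
  v <- validate_acquisition(img, list(expected_kvp = 90))
  expect_length(v, 1)
  expect_match(v, "kVp")
  img2 <- make_test_image()
  img2$metadata$kvp <- NA_real_
  expect_match(validate_acquisition(img2, list(expected_kvp = 80)),
               "kVp not recorded")
  v3 <- validate_acquisition(img, list(detector_id = "OTHER",
                                       modality = "mammography"))
  expect_length(v3, 2)
})

test_that("QC CSV round-trips records field-for-field", {
  f <- tempfile(fileext = ".csv")
  write_qc_csv(list(), f)
  expect_identical(readLines(f), paste(phantomqc:::QC_CSV_COLUMNS, collapse = ","))
  expect_length(read_qc_csv(f), 0)

  recs <- list(
    qc_record("dev-1", as.POSIXct("2021-01-01 08:00:00", tz = "UTC"),
              kvp = 80, mas = 10.25, snr = 100.5, sdnr = 9.875,
              mtf50_h = 1.234567891234, dprime_small = 12.5,
              uniformity_flag = FALSE),
    qc_record("dev-1", as.POSIXct("2021-01-08 08:00:00", tz = "UTC"),
              kvp = 80, sdnr = 9.5, organ_dose = NA),
    qc_record("dev-2", as.POSIXct("2021-01-15 08:00:00", tz = "UTC"),
              exposure_index = 400, uniformity_flag = TRUE))
  write_qc_csv(recs, f)
  back <- read_qc_csv(f)
  expect_equal(back, recs)
  # absent organ_dose is an empty cell
  expect_match(readLines(f)[3], ",,")
  expect_true(is.na(back[[2]]$organ_dose))
})

test_that("QC CSV round-trip holds for randomized records (property)", {
  set.seed(42)
  for (k in 1:20) {
    args <- list(device_key = paste0("d", k),
                 acquisition_datetime = as.POSIXct("2020-01-01", tz = "UTC") +
                   round(runif(1, 0, 3e7)))
    for (nm in sample(phantomqc:::QC_NUMERIC_COLUMNS, 8)) {
      args[[nm]] <- signif(runif(1, -5, 500), sample(3:15, 1))
    }
    rec <- do.call(qc_record, args)
    f <- tempfile(fileext = ".csv")
    write_qc_csv(list(rec), f)
    expect_equal(read_qc_csv(f)[[1]], rec)
  }
})

test_that("malformed CSV rows raise errors naming the row", {
  f <- tempfile(fileext = ".csv")
  write_qc_csv(make_records(c(1, 2)), f)
  lines <- readLines(f)
  lines[3] <- paste0(lines[3], ",extra-field")
  writeLines(lines, f)
  expect_error(read_qc_csv(f), "row 3")
  lines2 <- readLines(f)[1:2]
  lines2[2] <- sub("^dev-1,([^,]*),", "dev-1,\\1,not-a-number", lines2[2])
  f2 <- tempfile(fileext = ".csv")
  writeLines(lines2, f2)
  expect_error(read_qc_csv(f2), "row 2")
  f3 <- tempfile(fileext = ".csv")
  writeLines("wrong,header", f3)
  expect_error(read_qc_csv(f3), "header")
})
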