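# End-to-end QC workflows: image -> QcRecord -> history -> limits/trends.

#' Default device configuration
#'
#' @param modality `"radiography"` or `"mammography"`
#' @param device_key device identifier used in records and history
#' @return list understood by [analyze_image()]; serializable as JSON
#' @export
default_device_config <- function(modality = "radiography",
                                  device_key = "device-1") {
  list(device_key = device_key,
       modality = modality,
       expected_kvp = if (modality == "radiography") 80 else 28,
       phantom = unclass(phantom_spec(modality)),
       pixel_spacing_mm = NULL,
       tag_map = list(),
       disk_diameters_mm = default_disk_diameters(modality),
       viewing_distance_mm = 400,
       contrast_nominal = NULL,
       dprime_constant_placement = "as_printed",
       variance_threshold = 5)
}

#' Read a device configuration from JSON
#' @param path JSON file with any subset of the [default_device_config()]
#'   fields (missing fields take defaults)
#' @export
read_device_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_device_config(cfg$modality %||% "radiography",
                                cfg$device_key %||% "device-1")
  for (nm in names(cfg)) {
    if (nm == "phantom") {
      for (f in names(cfg$phantom)) base$phantom[[f]] <- cfg$phantom[[f]]
    } else base[[nm]] <- cfg[[nm]]
  }
  base
}

config_phantom_spec <- function(device_config) {
  ph <- device_config$phantom
  do.call(phantom_spec, ph[!vapply(ph, is.null, logical(1))])
}

#' Analyze a phantom image into a full QC report
#'
#' Pipeline: read, validate acquisition, locate ROIs, SDNR/SNR, horizontal
#' and vertical slanted-edge MTF, detrended NNPS, common frequency grid,
#' NPWE d' for both disk diameters, variance map. Any stage's hard error
#' aborts with a stage-named message; the analysis itself is deterministic,
#' so re-running on the same input reproduces identical metrics.
#'
#' @param path DICOM/TIFF file, or a [phantom_image] directly
#' @param device_config list from [default_device_config()] /
#'   [read_device_config()]
#' @return object of class `analysis_report`: `record` ([qc_record()]),
#'   `roiset`, `mtf` (h/v/averaged curves), `nnps`, `char_freq` (h/v),
#'   `dprime`, `variance` (defect summary), `violations`, `warnings`
#' @export
analyze_image <- function(path, device_config = default_device_config()) {
  warnings <- character()
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  image <- stage("read", {
    if (inherits(path, "phantom_image")) path
    else grab(read_phantom_image(path, device_config))
  })
  violations <- stage("validate", validate_acquisition(image, list(
    expected_kvp = device_config$expected_kvp,
    modality = device_config$modality,
    detector_id = device_config$detector_id)))
  spec <- config_phantom_spec(device_config)
  roiset <- stage("locate", grab(locate_rois(image, spec)))
  warnings <- c(warnings, roiset$warnings)

  bg <- stage("roi-stats", roi_stats(image, roiset$background_roi))
  al <- stage("roi-stats", roi_stats(image, roiset$al_roi))
  sdnr <- stage("sdnr", compute_sdnr(bg, al))
  snr <- stage("snr", compute_snr(bg))

  band <- min(32, floor(roiset$cu_square$side_px * 0.3))
  mtf_for <- function(seg_a, seg_b) {
    a1 <- grab(estimate_edge_angle(image, seg_a))
    warnings <<- c(warnings, attr(a1, "warnings"))
    esf <- build_oversampled_esf(image, seg_a, a1, band_halfwidth_px = band)
    m1 <- compute_presampled_mtf(esf)
    a2 <- grab(estimate_edge_angle(image, seg_b))
    warnings <<- c(warnings, attr(a2, "warnings"))
    esf2 <- build_oversampled_esf(image, seg_b, a2, band_halfwidth_px = band)
    m2 <- compute_presampled_mtf(esf2)
    out <- m1
    out$values <- (m1$values + m2$values) / 2
    out$edge_angle_deg <- mean(c(a1, a2))
    out
  }
  mtf_h <- stage("mtf-horizontal",
                 mtf_for(roiset$edge_segments$left, roiset$edge_segments$right))
  mtf_v <- stage("mtf-vertical",
                 mtf_for(roiset$edge_segments$top, roiset$edge_segments$bottom))
  mtf_avg <- stage("mtf-average", average_mtf(mtf_h, mtf_v))
  cf_h <- characteristic_frequencies(mtf_h)
  cf_v <- characteristic_frequencies(mtf_v)

  nnps <- stage("nnps", compute_nnps(extract_roi(image$pixels, roiset$nnps_region),
                                     image$pixel_spacing_mm[1]))
  cg <- stage("common-grid", common_grid(mtf_avg, nnps))

  contrast <- device_config$contrast_nominal %||%
    (abs(bg$mean_signal - al$mean_signal) / bg$mean_signal)
  dd <- device_config$disk_diameters_mm
  dprime <- stage("dprime", vapply(dd, function(D)
    compute_dprime(cg$mtf, cg$nnps,
                   detection_task(contrast, D, device_config$viewing_distance_mm),
                   device_config$dprime_constant_placement),
    numeric(1)))

  vmap <- stage("variance-map", compute_variance_map(image, roiset))
  defects <- stage("variance-map",
                   flag_defects(vmap, device_config$variance_threshold))

  md <- image$metadata
  record <- qc_record(
    device_key = device_config$device_key %||% "device-1",
    acquisition_datetime = md$acquisition_datetime,
    kvp = md$kvp, mas = md$tube_load_mas, exposure_index = md$exposure_index,
    organ_dose = md$organ_dose, entrance_dose = md$entrance_dose,
    snr = snr, sdnr = sdnr,
    mtf50_h = cf_h$f50, mtf20_h = cf_h$f20, mtf10_h = cf_h$f10,
    mtf50_v = cf_v$f50, mtf20_v = cf_v$f20, mtf10_v = cf_v$f10,
    dprime_small = dprime[1], dprime_large = dprime[2],
    uniformity_flag = nrow(defects) > 0)

  structure(list(record = record, roiset = roiset,
                 mtf = list(horizontal = mtf_h, vertical = mtf_v,
                            averaged = cg$mtf),
                 nnps = nnps, char_freq = list(horizontal = cf_h, vertical = cf_v),
                 dprime = stats::setNames(dprime, c("small", "large")),
                 contrast = contrast,
                 variance = list(map = vmap, defects = defects),
                 violations = violations, warnings = unique(warnings)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  r <- x$record
  cat("<analysis_report>\n")
  cat(sprintf("  SNR %.2f | SDNR %.2f | d'(small) %.2f | d'(large) %.2f\n",
              r$snr, r$sdnr, r$dprime_small, r$dprime_large))
  cat(sprintf("  MTF50/20/10 (h): %.3f / %.3f / %.3f cycles/mm\n",
              r$mtf50_h, r$mtf20_h, r$mtf10_h))
  cat(sprintf("  MTF50/20/10 (v): %.3f / %.3f / %.3f cycles/mm\n",
              r$mtf50_v, r$mtf20_v, r$mtf10_v))
  cat(sprintf("  defects flagged: %d | violations: %d | warnings: %d\n",
              nrow(x$variance$defects), length(x$violations), length(x$warnings)))
  for (v in x$violations) cat("  VIOLATION:", v, "\n")
  invisible(x)
}

#' Run one QC session: analyze, append to history, check limits and trends
#'
#' The history CSV is only replaced after the analysis succeeds (a failed
#' session leaves it unmodified).
#'
#' @param path image file or [phantom_image]
#' @param history_csv per-device append-only history (created on first use)
#' @param device_config device configuration list
#' @param policy limit policy (`"pct10"`, `"pct15"`, `"sd2"`)
#' @param n_baseline sessions forming the baseline
#' @param trend_window monotone-run length for trend detection
#' @return list of class `session_result`: `status` (0 in control, 2 limit
#'   violation, 3 trend flag), `report`, `flags`, `trends`
#' @export
run_session <- function(path, history_csv,
                        device_config = default_device_config(),
                        policy = "pct10", n_baseline = 10, trend_window = 6L) {
  report <- analyze_image(path, device_config)
  records <- if (file.exists(history_csv)) read_qc_csv(history_csv) else list()
  records <- c(records, list(report$record))

  status <- 0L
  flags <- list(); trends <- list()
  df <- qc_records_to_df(records)
  for (m in CHART_METRICS) {
    v <- df[[m]]
    if (sum(!is.na(v)) < max(5, n_baseline)) next
    bl <- establish_baseline(records, m, n_baseline)
    ch <- tryCatch(control_chart(df$device_key[1], m, seq_along(v), v, bl, policy),
                   error = function(e) NULL)
    if (is.null(ch)) next
    fl <- tryCatch(apply_limits(ch), error = function(e) NULL)
    if (is.null(fl)) next
    flags[[m]] <- fl
    if (fl[length(fl)] != "ok") status <- 2L
    trends[[m]] <- detect_trend(ch, trend_window)
  }
  if (status == 0L &&
      any(vapply(trends, function(t) t$monotone_run || t$ma_drift, logical(1))))
    status <- 3L

  tmp <- paste0(history_csv, ".tmp")
  write_qc_csv(records, tmp)
  file.rename(tmp, history_csv)

  structure(list(status = status, report = report, flags = flags,
                 trends = trends, n_records = length(records)),
            class = "session_result")
}
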