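# Per-device metric history, baselines, control limits, trend rules and
# chart rendering (the role of the spreadsheet workbook in the original
# workflow).

CHART_METRICS <- c("mas", "kvp", "organ_dose", "entrance_dose",
                   "exposure_index", "snr", "sdnr",
                   "mtf50_h", "mtf20_h", "mtf10_h",
                   "mtf50_v", "mtf20_v", "mtf10_v",
                   "dprime_small", "dprime_large")

#' Establish a metric baseline from the first sessions
#'
#' @param records list of [qc_record()]s in chronological order
#' @param metric_name one of the tracked metric fields
#' @param n_baseline number of leading records forming the baseline
#'   (default 10; at least 5 required)
#' @return list `(mean, sd, n)`; the baseline is meant to be stored
#'   immutably with the chart and never recomputed as records accrue
#' @export
establish_baseline <- function(records, metric_name, n_baseline = 10) {
  vals <- vapply(records, function(r) as.numeric(r[[metric_name]]), numeric(1))
  vals <- vals[!is.na(vals)]
  if (n_baseline < 5)
    stop("baseline needs at least 5 sessions")
  if (length(vals) < n_baseline)
    stop("only ", length(vals), " usable sessions for metric '", metric_name,
         "'; ", n_baseline, " required to establish a baseline")
  v <- vals[seq_len(n_baseline)]
  list(mean = mean(v), sd = stats::sd(v), n = n_baseline)
}

#' Construct a control chart for one metric
#'
#' @param device_key device identifier
#' @param metric_name tracked metric field
#' @param timestamps `POSIXct` session times
#' @param values metric values (NA allowed, skipped in flags)
#' @param baseline list `(mean, sd)` from [establish_baseline()]
#' @param limit_policy `"pct10"`, `"pct15"` or `"sd2"`
#' @param ma_window moving-average window (sessions)
#' @return object of class `control_chart`
#' @export
control_chart <- function(device_key, metric_name, timestamps, values,
                          baseline, limit_policy = c("pct10", "pct15", "sd2"),
                          ma_window = 5L) {
  limit_policy <- match.arg(limit_policy)
  stopifnot(length(timestamps) == length(values))
  structure(list(device_key = device_key, metric_name = metric_name,
                 timestamps = timestamps, values = as.numeric(values),
                 baseline_mean = baseline$mean, baseline_sd = baseline$sd,
                 limit_policy = limit_policy, ma_window = as.integer(ma_window)),
            class = "control_chart")
}

#' Control limits implied by a chart's policy
#' @param chart a `control_chart`
#' @return `c(lower, upper)`
#' @export
chart_limits <- function(chart) {
  m <- chart$baseline_mean
  switch(chart$limit_policy,
    pct10 = c(m * 0.9, m * 1.1),
    pct15 = c(m * 0.85, m * 1.15),
    sd2 = {
      if (is.na(chart$baseline_sd) || chart$baseline_sd <= 0)
        stop("sd2 limit policy requires a positive baseline SD ",
             "(constant baseline values cannot define limits)")
      c(m - 2 * chart$baseline_sd, m + 2 * chart$baseline_sd)
    })
}

#' Flag points outside the control limits
#'
#' A point strictly outside the limits is flagged `"high"`/`"low"`; a point
#' exactly on a limit is in control (documented boundary rule); `NA` values
#' flag as `"ok"`.
#'
#' @param chart a `control_chart`
#' @return character vector of per-point flags (`ok`/`high`/`low`)
#' @export
apply_limits <- function(chart) {
  lim <- chart_limits(chart)
  v <- chart$values
  flags <- rep("ok", length(v))
  flags[!is.na(v) & v > lim[2]] <- "high"
  flags[!is.na(v) & v < lim[1]] <- "low"
  flags
}

#' Detect monotone runs and moving-average drift
#'
#' Two separately reported criteria: a strictly monotone run of at least
#' `window` consecutive points, and a moving average (window `ma_window`
#' from the chart) drifting more than one baseline SD from the baseline
#' mean.
#'
#' @param chart a `control_chart`
#' @param window monotone-run length (default 6)
#' @return list `monotone_run` (logical), `run_length`, `run_direction`,
#'   `ma_drift` (logical), `max_ma_deviation_sd`
#' @export
detect_trend <- function(chart, window = 6L) {
  v <- chart$values[!is.na(chart$values)]
  n <- length(v)
  run_len <- 0L; best <- 1L; dirn <- "none"
  if (n >= 2) {
    s <- sign(diff(v))
    r <- rle(s)
    keep <- r$values != 0
    if (any(keep)) {
      best <- max(r$lengths[keep]) + 1L
      dirn <- if (r$values[keep][which.max(r$lengths[keep])] > 0) "up" else "down"
    }
    run_len <- best
  }
  monotone <- n >= window && run_len >= window
  ma_drift <- FALSE; max_dev <- NA_real_
  if (!is.na(chart$baseline_sd) && chart$baseline_sd > 0 && n >= chart$ma_window) {
    ma <- stats::filter(v, rep(1 / chart$ma_window, chart$ma_window), sides = 1)
    dev <- abs(ma - chart$baseline_mean) / chart$baseline_sd
    max_dev <- max(dev, na.rm = TRUE)
    ma_drift <- max_dev > 1
  }
  list(monotone_run = monotone, run_length = run_len,
       run_direction = if (monotone) dirn else "none",
       ma_drift = ma_drift, max_ma_deviation_sd = max_dev)
}

#' Render control charts for a device history
#'
#' One PNG per tracked metric plus an overview grid; deterministic output
#' for fixed input.
#'
#' @param records list of [qc_record()]s in chronological order
#' @param out_dir output directory (created if needed)
#' @param limit_policy limit policy for all charts
#' @param n_baseline sessions forming the baseline (charts without enough
#'   history are drawn without limits)
#' @return character vector of files written
#' @export
render_charts <- function(records, out_dir, limit_policy = "pct10",
                          n_baseline = 10) {
  stopifnot(length(records) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- qc_records_to_df(records)
  ts <- seq_len(nrow(df))
  metrics <- CHART_METRICS[vapply(CHART_METRICS, function(m)
    any(!is.na(df[[m]])), logical(1))]
  files <- character()

  plot_one <- function(m, cex = 1) {
    v <- df[[m]]
    chart <- NULL
    flags <- rep("ok", length(v))
    lim <- NULL
    if (sum(!is.na(v)) >= max(5, n_baseline)) {
      bl <- establish_baseline(records, m, n_baseline)
      chart <- control_chart(df$device_key[1], m, ts, v, bl, limit_policy)
      lim <- tryCatch(chart_limits(chart), error = function(e) NULL)
      if (!is.null(lim)) flags <- apply_limits(chart)
    }
    ylim <- range(c(v, lim), na.rm = TRUE)
    graphics::plot(ts, v, type = "b", pch = 19, cex = cex,
                   col = ifelse(flags == "ok", "black", "red"),
                   xlab = "session", ylab = m, main = m, ylim = ylim)
    if (!is.null(lim)) {
      graphics::abline(h = lim, lty = 2, col = "red")
      graphics::abline(h = chart$baseline_mean, lty = 3, col = "blue")
    }
  }

  for (m in metrics) {
    f <- file.path(out_dir, paste0(m, ".png"))
    grDevices::png(f, width = 640, height = 400, type = "cairo")
    graphics::par(mar = c(4, 4, 2, 1))
    plot_one(m)
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(out_dir, "overview.png")
  nc <- 4L; nr <- ceiling(length(metrics) / nc)
  grDevices::png(f, width = 1280, height = max(1, nr) * 240, type = "cairo")
  graphics::par(mfrow = c(nr, nc), mar = c(2, 4, 2, 1))
  for (m in metrics) plot_one(m, cex = 0.6)
  grDevices::dev.off()
  c(files, f)
}
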