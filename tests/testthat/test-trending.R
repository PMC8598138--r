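# Baselines, control limits, trend rules, chart rendering.

test_that("baseline mean/SD and failure modes", {
  recs <- make_records(c(98, 100, 102, 100, 100))
  bl <- establish_baseline(recs, "sdnr", n_baseline = 5)
  expect_equal(bl$mean, 100)
  expect_equal(bl$sd, sqrt(2))
  expect_error(establish_baseline(recs, "sdnr", n_baseline = 6), "5 usable|required")
  expect_error(establish_baseline(recs[1:3], "sdnr", n_baseline = 5), "required")
  expect_error(establish_baseline(recs, "sdnr", n_baseline = 3), "at least 5")
})

test_that("limit policies flag strictly-outside points only", {
  recs <- make_records(rep(100, 5))
  bl <- establish_baseline(recs, "sdnr", 5)   # mean 100, sd 0
  mk <- function(vals, policy, sd = bl$sd)
    control_chart("d", "sdnr", seq_along(vals), vals,
                  list(mean = 100, sd = sd), policy)
  expect_identical(apply_limits(mk(c(100, 111, 89, 110, 90), "pct10")),
                   c("ok", "high", "low", "ok", "ok"))
  expect_identical(apply_limits(mk(c(114, 116, 85.0001), "pct15")),
                   c("ok", "high", "ok"))
  expect_identical(apply_limits(mk(c(109, 111), "sd2", sd = 5)),
                   c("ok", "high"))
  # sd2 with zero SD is a configuration error
  expect_error(apply_limits(mk(c(100), "sd2", sd = 0)), "SD")
  # NA points are not flagged
  expect_identical(apply_limits(mk(c(NA, 150), "pct10")), c("ok", "high"))
})

test_that("flags agree with a brute-force recheck on random series (property)", {
  set.seed(99)
  for (k in 1:200) {
    n <- sample(6:40, 1)
    vals <- rnorm(n, 100, 15)
    policy <- sample(c("pct10", "pct15", "sd2"), 1)
    bl <- list(mean = mean(vals[1:5]), sd = max(sd(vals[1:5]), 1e-6))
    ch <- control_chart("d", "m", seq_len(n), vals, bl, policy)
    got <- apply_limits(ch)
    lim <- switch(policy,
                  pct10 = bl$mean * c(0.9, 1.1),
                  pct15 = bl$mean * c(0.85, 1.15),
                  sd2 = bl$mean + c(-2, 2) * bl$sd)
    want <- ifelse(vals > lim[2], "high", ifelse(vals < lim[1], "low", "ok"))
    expect_identical(got, want)
  }
})

test_that("monotone runs and moving-average drift are reported separately", {
  bl <- list(mean = 100, sd = 2)
  down <- control_chart("d", "m", 1:8, c(107, 106, 105, 104, 103, 102, 101, 100), bl)
  tr <- detect_trend(down, window = 6)
  expect_true(tr$monotone_run)
  expect_identical(tr$run_direction, "down")
  flat <- control_chart("d", "m", 1:8, c(100, 101, 100, 101, 100, 101, 100, 101), bl)
  expect_false(detect_trend(flat, window = 6)$monotone_run)
  drifty <- control_chart("d", "m", 1:12,
                          c(100, 100, 100, 100, 100, 100, 104, 103, 104, 103, 104, 103), bl)
  trd <- detect_trend(drifty, window = 6)
  expect_false(trd$monotone_run)
  expect_true(trd$ma_drift)
})

test_that("i.i.d. noise rarely triggers the monotone-run rule", {
  set.seed(7)
  hits <- mean(vapply(1:400, function(i) {
    vals <- rnorm(20, 100, 5)
    ch <- control_chart("d", "m", 1:20, vals, list(mean = 100, sd = 5))
    detect_trend(ch, window = 6)$monotone_run
  }, logical(1)))
  expect_lt(hits, 0.05)
})

test_that("slow drift trips the trend rule before the pct10 limit", {
  # SDNR decaying 1%/session from 100 with small noise: the moving average
  # leaves the 1-SD band long before any point crosses the 10% limit
  set.seed(3)
  vals <- 100 * (1 - 0.01 * (0:19)) + rnorm(20, 0, 0.5)
  recs <- make_records(vals)
  bl <- establish_baseline(recs, "sdnr", 5)
  first_limit <- NA; first_trend <- NA
  for (i in 6:20) {
    ch <- control_chart("d", "sdnr", 1:i, vals[1:i], bl, "pct10")
    if (is.na(first_limit) && any(apply_limits(ch) != "ok")) first_limit <- i
    tr <- detect_trend(ch, window = 6)
    if (is.na(first_trend) && (tr$monotone_run || tr$ma_drift)) first_trend <- i
  }
  expect_false(is.na(first_trend))
  expect_true(is.na(first_limit) || first_trend < first_limit)
})

test_that("baseline is immutable as records accrue", {
  recs <- make_records(c(98, 100, 102, 100, 100, 300, 400))
  expect_identical(establish_baseline(recs, "sdnr", 5),
                   establish_baseline(recs[1:5], "sdnr", 5))
})

test_that("chart rendering is deterministic and handles single records", {
  recs <- make_records(rnorm(12, 10, 0.5))
  d1 <- file.path(tempdir(), "charts1"); d2 <- file.path(tempdir(), "charts2")
  f1 <- render_charts(recs, d1)
  f2 <- render_charts(recs, d2)
  expect_true(all(file.exists(f1)))
  expect_identical(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readBin(f1[k], "raw", file.info(f1[k])$size),
                     readBin(f2[k], "raw", file.info(f2[k])$size))
  # single record: a chart with one point and no limits
  f3 <- render_charts(make_records(5), file.path(tempdir(), "charts3"))
  expect_true(any(grepl("sdnr.png", f3, fixed = TRUE)))
  expect_true(any(grepl("overview.png", f3, fixed = TRUE)))
})
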