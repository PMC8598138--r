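# Slanted-edge MTF, detrending, NNPS (closed-form oracles).

ny <- 5  # Nyquist at 0.1 mm pitch, cycles/mm

test_that("edge angle is recovered, sign convention and range warnings hold", {
  sim <- simulate_phantom_image(edge_config(sigma = 0.3, angle = 3, seed = 1))
  seg <- sim$truth$roi_truth$edge_segments$left
  a <- estimate_edge_angle(sim$image, seg)
  expect_lt(abs(a - 3), 0.1)
  expect_length(attr(a, "warnings"), 0)

  # all four edges report the same square rotation
  for (s in sim$truth$roi_truth$edge_segments)
    expect_lt(abs(estimate_edge_angle(sim$image, s) - 3), 0.1)

  # mirroring the image negates the angle
  img_m <- sim$image
  nc <- ncol(img_m$pixels)
  img_m$pixels <- img_m$pixels[, nc:1]
  seg_m <- seg
  seg_m$p1[2] <- nc + 1 - seg$p1[2]
  seg_m$p2[2] <- nc + 1 - seg$p2[2]
  expect_lt(abs(estimate_edge_angle(img_m, seg_m) + 3), 0.1)

  # an un-slanted edge is flagged out of range
  sim0 <- simulate_phantom_image(edge_config(sigma = 0.3, angle = 0, seed = 1))
  a0 <- estimate_edge_angle(sim0$image, sim0$truth$roi_truth$edge_segments$left)
  expect_match(paste(attr(a0, "warnings"), collapse = " "), "outside")
})

test_that("ESF of an ideal step is a monotone step of width <= 1 px", {
  sim <- simulate_phantom_image(edge_config(sigma = 0, seed = 1))
  seg <- sim$truth$roi_truth$edge_segments$left
  esf <- build_oversampled_esf(sim$image, seg, 3, band_halfwidth_px = 34)
  v <- esf$values
  lo <- mean(v[1:50]); hi <- mean(v[(length(v) - 49):length(v)])
  i10 <- min(which(v > lo + 0.1 * (hi - lo)))
  i90 <- min(which(v > lo + 0.9 * (hi - lo)))
  expect_lt(esf$dist_px[i90] - esf$dist_px[i10], 1)
  # ordered low -> high
  expect_lt(v[1], v[length(v)])
})

test_that("ESF of a Gaussian-blurred edge matches the Gaussian CDF", {
  sigma_mm <- 0.5
  sim <- simulate_phantom_image(edge_config(sigma = sigma_mm, seed = 1))
  seg <- sim$truth$roi_truth$edge_segments$left
  esf <- build_oversampled_esf(sim$image, seg, 3, band_halfwidth_px = 45)
  v <- esf$values
  lo <- mean(v[1:30]); hi <- mean(v[(length(v) - 29):length(v)])
  # blur sigma in px, plus the 1-px aperture variance (1/12)
  s_eff <- sqrt((sigma_mm / 0.1)^2 + 1 / 12)
  d0 <- esf$dist_px[min(which(v >= (lo + hi) / 2))]
  model <- lo + (hi - lo) * pnorm((esf$dist_px - d0) / s_eff)
  rms <- sqrt(mean(((v - model) / (hi - lo))^2))
  expect_lt(rms, 0.01)
})

test_that("doubling the band width barely changes the ESF", {
  sim <- simulate_phantom_image(edge_config(sigma = 0.3, seed = 1))
  seg <- sim$truth$roi_truth$edge_segments$left
  e1 <- build_oversampled_esf(sim$image, seg, 3, band_halfwidth_px = 25)
  e2 <- build_oversampled_esf(sim$image, seg, 3, band_halfwidth_px = 50)
  common <- intersect(round(e1$dist_px * 10), round(e2$dist_px * 10))
  v1 <- e1$values[match(common, round(e1$dist_px * 10))]
  v2 <- e2$values[match(common, round(e2$dist_px * 10))]
  contrast <- diff(range(v2))
  expect_lt(sqrt(mean((v1 - v2)^2)) / contrast, 0.005)
})

test_that("ESF band clipped by the image border is an error", {
  sim <- simulate_phantom_image(edge_config(sigma = 0.2, seed = 1))
  seg <- sim$truth$roi_truth$edge_segments$left
  expect_error(build_oversampled_esf(sim$image, seg, 3, band_halfwidth_px = 300),
               "border|bounds")
})

test_that("measured MTF matches the Gaussian x aperture oracle", {
  for (sigma in c(0.2, 0.5)) {
    sim <- simulate_phantom_image(edge_config(sigma = sigma, seed = 1))
    seg <- sim$truth$roi_truth$edge_segments$left
    a <- estimate_edge_angle(sim$image, seg)
    esf <- build_oversampled_esf(sim$image, seg, a, band_halfwidth_px = 50)
    mtf <- compute_presampled_mtf(esf)
    expect_equal(mtf$values[1], 1)
    keep <- mtf$frequencies <= 0.8 * ny
    ref <- sim$truth$analytic_mtf(mtf$frequencies)
    expect_lt(sqrt(mean((mtf$values[keep] - ref[keep])^2)), 0.02)
  }
  # sigma = 0: aperture-only MTF ~ |sinc|
  sim0 <- simulate_phantom_image(edge_config(sigma = 0, seed = 1))
  seg <- sim0$truth$roi_truth$edge_segments$left
  esf0 <- build_oversampled_esf(sim0$image, seg, 3, band_halfwidth_px = 34)
  mtf0 <- compute_presampled_mtf(esf0)
  u <- mtf0$frequencies
  ref0 <- ifelse(u == 0, 1, abs(sin(pi * 0.1 * u) / (pi * 0.1 * u)))
  keep <- u <= 0.8 * ny
  expect_lt(sqrt(mean((mtf0$values[keep] - ref0[keep])^2)), 0.02)
})

test_that("zero-contrast edge raises a no-signal error", {
  cfg <- edge_config(sigma = 0.2, seed = 1, cu_transmission = 1)
  sim <- simulate_phantom_image(cfg)
  seg <- sim$truth$roi_truth$edge_segments$left
  expect_error(build_oversampled_esf(sim$image, seg, 3), "edge|crossings")
})

test_that("MTF is insensitive to the edge angle within 2-5 degrees", {
  m2 <- local({
    sim <- simulate_phantom_image(edge_config(sigma = 0.5, angle = 2, seed = 1))
    seg <- sim$truth$roi_truth$edge_segments$left
    compute_presampled_mtf(build_oversampled_esf(sim$image, seg,
      estimate_edge_angle(sim$image, seg), band_halfwidth_px = 50))
  })
  m5 <- local({
    sim <- simulate_phantom_image(edge_config(sigma = 0.5, angle = 5, seed = 1))
    seg <- sim$truth$roi_truth$edge_segments$left
    compute_presampled_mtf(build_oversampled_esf(sim$image, seg,
      estimate_edge_angle(sim$image, seg), band_halfwidth_px = 50))
  })
  keep <- m2$frequencies <= 0.8 * ny
  expect_lt(sqrt(mean((m2$values[keep] - m5$values[keep])^2)), 0.02)
})

test_that("characteristic frequencies: closed-form crossings and ordering", {
  u <- seq(0, 5, length.out = 257)
  sigma <- 0.35
  mtf <- make_mtf_curve(u, exp(-2 * pi^2 * sigma^2 * u^2))
  cf <- characteristic_frequencies(mtf)
  expect_lt(cf$f50, cf$f20)
  expect_lt(cf$f20, cf$f10)
  expect_lt(abs(cf$f50 / cf$f10 - sqrt(log(2) / log(10))), 0.01)
  f50_closed <- sqrt(log(2)) / (sqrt(2) * pi * sigma)
  expect_lt(abs(cf$f50 / f50_closed - 1), 0.01)
  # level never crossed -> absent
  flat <- make_mtf_curve(u, rep(0.65, length(u)))
  cf2 <- characteristic_frequencies(flat)
  expect_true(is.na(cf2$f50))
})

test_that("detrending removes planar ramps exactly and leaves noise alone", {
  n <- 256
  ramp <- outer(seq_len(n) * 0.3, seq_len(n) * -0.7, "+") + 1000
  out <- detrend_region(ramp)
  expect_lt(sd(out), 1e-6 * diff(range(ramp)))
  expect_equal(mean(out), mean(ramp))

  set.seed(1)
  noise <- matrix(rnorm(n * n, 1000, 10), n, n)
  out2 <- detrend_region(noise)
  expect_lt(abs(var(as.vector(out2)) / var(as.vector(noise)) - 1), 0.01)
  expect_equal(mean(out2), mean(noise))
})

test_that("white-noise NNPS is flat at sigma^2 p^2 / M^2 with Parseval identity", {
  sim <- simulate_phantom_image(uniform_config(seed = 2, size = 512,
                                               gain = 0, sd = 100))
  nn <- compute_nnps(sim$image$pixels, 0.1)
  theory <- 100^2 * 0.1^2 / 10000^2
  mid <- nn$frequencies > 0.1 * ny & nn$frequencies < 0.9 * ny
  expect_lt(abs(mean(nn$values[mid]) / theory - 1), 0.05)
  expect_lt(abs(nnps_parseval_sum(nn) /
                  (var(as.vector(sim$image$pixels)) / mean(sim$image$pixels)^2) - 1),
            0.02)
  expect_true(all(nn$values >= 0))
  # directional cuts see the same level
  for (d in c("horizontal", "vertical"))
    expect_lt(abs(mean(nn$cuts[[d]][mid]) / theory - 1), 0.1)
})

test_that("NNPS of a constant region is zero; degenerate inputs error", {
  const <- matrix(500, 256, 256)
  nn <- compute_nnps(const, 0.1)
  expect_true(all(nn$values == 0))
  expect_error(compute_nnps(matrix(-1, 256, 256), 0.1), "mean")
  expect_error(compute_nnps(matrix(1, 100, 100), 0.1), "256")
})

test_that("two seeds of one config agree within Monte-Carlo bands", {
  n1 <- compute_nnps(simulate_phantom_image(uniform_config(seed = 10,
    size = 512, gain = 0, sd = 100))$image$pixels, 0.1)
  n2 <- compute_nnps(simulate_phantom_image(uniform_config(seed = 11,
    size = 512, gain = 0, sd = 100))$image$pixels, 0.1)
  mid <- n1$frequencies > 0.05 * ny
  rel <- abs(n1$values[mid] - n2$values[mid]) /
    ((n1$values[mid] + n2$values[mid]) / 2)
  expect_lt(mean(rel), 0.15)
})

test_that("common_grid interpolation is exact on shared points and linear segments", {
  u_f <- seq(0, 5, length.out = 129)
  mtf <- make_mtf_curve(u_f, 1 - u_f / 10)
  nn <- make_nnps_curve(u_f[seq(1, 129, by = 2)], rep(1e-6, 65))
  cg <- common_grid(mtf, nn)
  expect_equal(cg$mtf$frequencies, nn$frequencies)
  expect_equal(cg$mtf$values, 1 - nn$frequencies / 10)
  # averaging identical directional curves is the identity
  avg <- average_mtf(mtf, mtf)
  expect_equal(avg$values, mtf$values)
  expect_identical(avg$direction, "averaged")
})
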