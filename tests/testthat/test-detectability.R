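# NPWE detectability index: shape function, eye filter, Eq-level oracle.

test_that("disk shape function: area limit, first Bessel zero, scaling law", {
  expect_equal(disk_shape_function(1, 0), pi / 4)
  # first zero of J1(pi D u) at pi D u = 3.8317 -> u = 1.2197 / D
  for (D in c(0.3, 1, 4)) {
    u0 <- 1.2197 / D
    us <- seq(0.98 * u0, 1.02 * u0, length.out = 400)
    s <- disk_shape_function(D, us)
    i <- which(s[-length(s)] * s[-1] <= 0)[1]
    expect_lt(abs(us[i] / u0 - 1), 0.005)
  }
  # Fourier similarity: S(u; 2D) = 4 * S(2u; D)
  u <- seq(0, 3, by = 0.01)
  expect_equal(disk_shape_function(2 * 0.7, u),
               4 * disk_shape_function(0.7, 2 * u))
})

test_that("eye filter peaks at 4 cycles/degree and is band-pass", {
  d <- 400
  u <- seq(0, 5, by = 1e-3)
  v <- visual_transfer_function(u, d)
  expect_equal(v[1], 0)
  expect_equal(max(v), 1, tolerance = 1e-6)
  f_deg <- u[which.max(v)] * d * pi / 180
  expect_lt(abs(f_deg - 4), 0.05)
  # halving the distance moves the peak to twice the spatial frequency
  v2 <- visual_transfer_function(u, d / 2)
  expect_lt(abs(u[which.max(v2)] / (2 * u[which.max(v)]) - 1), 0.01)
  # single interior maximum
  expect_equal(sum(diff(sign(diff(v))) != 0), 1)
})

test_that("d' matches an independent quadrature oracle for flat curves", {
  u <- seq(0, 5, length.out = 129)
  mtf <- make_mtf_curve(u, rep(1, 129))
  N0 <- 2.5e-6
  nnps <- make_nnps_curve(u, rep(N0, 129))
  C <- 0.08; D <- 0.3
  task <- detection_task(C, D)
  task_flat <- task; task_flat$viewing_distance_mm <- 400
  # oracle: high-resolution adaptive quadrature of the printed expression
  # with VTF == 1 (drop the eye filter by evaluating the same formula
  # through the integrals directly)
  S2u <- function(x) disk_shape_function(D, x)^2 * x
  I <- stats::integrate(S2u, 0, 5, rel.tol = 1e-10)$value
  oracle <- 2 * pi * C * I / sqrt(N0 * I)
  # implementation with VTF forced to 1 via a 1x viewing-distance trick is
  # not possible; instead evaluate the trapezoid ratio directly
  trapz <- function(y) sum(diff(u) * (head(y, -1) + tail(y, -1)) / 2)
  I1 <- trapz(S2u(u)); I2 <- trapz(S2u(u) * N0)
  dp_impl_flat <- 2 * pi * C * I1 / sqrt(I2)
  expect_lt(abs(dp_impl_flat / oracle - 1), 0.005)

  # full implementation vs. oracle including the eye filter
  V <- function(x) visual_transfer_function(x, 400)
  I1o <- stats::integrate(function(x) S2u(x) * V(x)^2, 0, 5, rel.tol = 1e-10)$value
  I2o <- stats::integrate(function(x) S2u(x) * V(x)^4 * N0, 0, 5, rel.tol = 1e-10)$value
  oracle2 <- 2 * pi * C * I1o / sqrt(I2o)
  dp <- compute_dprime(mtf, nnps, task)
  expect_lt(abs(dp / oracle2 - 1), 0.005)
})

test_that("homogeneity laws hold to machine precision", {
  u <- seq(0, 5, length.out = 129)
  mtf <- make_mtf_curve(u, exp(-0.3 * u^2))
  nnps <- make_nnps_curve(u, 1e-6 * (1 + 0.2 * u / 5))
  t1 <- detection_task(0.1, 0.3)
  d1 <- compute_dprime(mtf, nnps, t1)
  expect_equal(compute_dprime(mtf, nnps, detection_task(0.3, 0.3)), 3 * d1)
  nnps_k <- nnps; nnps_k$values <- nnps$values * 4
  expect_equal(compute_dprime(mtf, nnps_k, t1), d1 / 2)
  expect_equal(compute_dprime(mtf, nnps, detection_task(0, 0.3)), 0)
  # repeat evaluation is bit-identical
  expect_identical(compute_dprime(mtf, nnps, t1), compute_dprime(mtf, nnps, t1))
})

test_that("grid refinement changes d' by < 0.5%", {
  u1 <- seq(0, 5, length.out = 129)
  u2 <- seq(0, 5, length.out = 257)
  shape <- function(u) exp(-0.25 * u^2)
  noise <- function(u) 1e-6 * (1 + 0.3 * exp(-u))
  t1 <- detection_task(0.1, 0.3)
  d1 <- compute_dprime(make_mtf_curve(u1, shape(u1)),
                       make_nnps_curve(u1, noise(u1)), t1)
  d2 <- compute_dprime(make_mtf_curve(u2, shape(u2)),
                       make_nnps_curve(u2, noise(u2)), t1)
  expect_lt(abs(d2 / d1 - 1), 0.005)
})

test_that("constant-placement option and degenerate inputs behave", {
  u <- seq(0, 5, length.out = 129)
  mtf <- make_mtf_curve(u, rep(1, 129))
  nnps <- make_nnps_curve(u, rep(1e-6, 129))
  t1 <- detection_task(0.1, 0.3)
  expect_equal(compute_dprime(mtf, nnps, t1, "radial") /
                 compute_dprime(mtf, nnps, t1, "as_printed"),
               sqrt(2 * pi) / (2 * pi))
  zero <- make_nnps_curve(u, rep(0, 129))
  expect_error(compute_dprime(mtf, zero, t1), "zero")
  off_grid <- make_nnps_curve(u[-1], rep(1e-6, 128))
  expect_error(compute_dprime(mtf, off_grid, t1), "grid")
})

test_that("d' increases monotonically with dose in simulation", {
  # white-noise NNPS scales as 1/M; flat-field level sets the noise
  dprimes <- vapply(c(4000, 8000, 16000), function(M) {
    sim <- simulate_phantom_image(uniform_config(seed = 3, size = 512, M = M,
                                                 gain = 1, sd = 10))
    nn <- compute_nnps(sim$image$pixels, 0.1)
    u <- nn$frequencies
    mtf <- make_mtf_curve(u, exp(-2 * pi^2 * 0.2^2 * u^2))
    compute_dprime(mtf, nn, detection_task(0.1, 0.3))
  }, numeric(1))
  expect_true(all(diff(dprimes) > 0))
})
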