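# Presampled MTF from the slanted Cu edge.
#
# Classic slanted-edge pipeline: subpixel 50%-threshold edge crossings give
# the edge angle; projecting a band of pixels onto the edge normal builds a
# supersampled edge spread function (ESF, 0.1-px bins); its centered finite
# difference is the line spread function (LSF); a Hann window centered on
# the LSF peak suppresses tail noise; the DFT magnitude, normalized at zero
# frequency, is the presampled MTF, finally binned onto the common frequency
# grid shared with the NNPS (spacing 1/(256 * pixel pitch)).

#' The common frequency grid shared by MTF and NNPS curves
#'
#' @param pixel_spacing_mm pixel pitch in mm
#' @param n transform length defining the grid (default 256)
#' @return frequencies in cycles/mm from 0 to Nyquist, spacing `1/(n*p)`
#' @export
common_frequency_grid <- function(pixel_spacing_mm, n = 256L) {
  (0:(n %/% 2L)) / (n * pixel_spacing_mm)
}

# Subpixel 50% edge crossings along an edge segment.
# Returns data.frame(t, crossing): for a near-vertical edge t is the row
# and crossing the (fractional) column, and vice versa.
edge_crossings <- function(image, edge_segment, search_halfwidth = 10L) {
  px <- image$pixels
  seg <- edge_segment
  vertical <- seg$orientation == "vertical"
  if (vertical) {
    t1 <- seg$p1[1]; t2 <- seg$p2[1]; x1 <- seg$p1[2]; x2 <- seg$p2[2]
  } else {
    t1 <- seg$p1[2]; t2 <- seg$p2[2]; x1 <- seg$p1[1]; x2 <- seg$p2[1]
  }
  ts <- seq(ceiling(min(t1, t2)), floor(max(t1, t2)))
  if (length(ts) < 8) stop("edge segment too short for angle estimation")
  x_exp <- x1 + (ts - t1) / (t2 - t1 + 1e-12) * (x2 - x1)
  lim <- if (vertical) ncol(px) else nrow(px)
  crossing <- rep(NA_real_, length(ts))
  for (k in seq_along(ts)) {
    xs <- round(x_exp[k]) + (-search_halfwidth:search_halfwidth)
    xs <- xs[xs >= 1 & xs <= lim]
    prof <- if (vertical) px[ts[k], xs] else px[xs, ts[k]]
    if (length(prof) < 5) next
    prof <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
    lo <- mean(prof[2:3]); hi <- mean(prof[(length(prof) - 2):(length(prof) - 1)])
    mid <- (lo + hi) / 2
    s <- prof - mid
    ix <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
    if (length(ix) == 0) next
    ix <- ix[which.min(abs(xs[ix] - x_exp[k]))]
    frac <- s[ix] / (s[ix] - s[ix + 1])
    crossing[k] <- xs[ix] + frac
  }
  ok <- is.finite(crossing)
  if (sum(ok) < 8) stop("could not find enough edge crossings (no clean edge?)")
  data.frame(t = ts[ok], crossing = crossing[ok])
}

#' Estimate the slant angle of a Cu edge
#'
#' Least-squares line through per-line subpixel 50% crossings. The angle is
#' the square's rotation relative to the pixel rows, clockwise positive
#' (origin at the top-left); all four edges of one square report the same
#' angle, and mirroring the image negates it.
#'
#' @param image a [phantom_image]
#' @param edge_segment one entry of `roi_set$edge_segments`
#' @return angle in degrees; warnings are attached via `attr(,"warnings")`
#'   for out-of-range angles (`|angle|` outside 1-7 degrees) or ragged fits
#' @export
estimate_edge_angle <- function(image, edge_segment) {
  cr <- edge_crossings(image, edge_segment)
  fit <- stats::lm.fit(cbind(1, cr$t), cr$crossing)
  slope <- fit$coefficients[2]
  angle <- if (edge_segment$orientation == "vertical")
    -atan(slope) * 180 / pi else atan(slope) * 180 / pi
  warnings <- character()
  rmse <- sqrt(mean(fit$residuals^2))
  if (rmse > 0.5)
    warnings <- c(warnings, sprintf("ragged edge: crossing fit RMSE %.2f px", rmse))
  if (abs(angle) < 1 || abs(angle) > 7)
    warnings <- c(warnings,
                  sprintf("edge angle %.2f deg outside [1, 7]; MTF unreliable", angle))
  attr(angle, "warnings") <- warnings
  names(angle) <- NULL
  angle
}

#' Build the oversampled edge spread function
#'
#' Every pixel in a band around the edge is projected onto the edge normal;
#' projected distances are binned at `bin_px` native-pixel pitch (default
#' 0.1); empty bins are filled by linear interpolation; the profile is
#' oriented low -> high signal.
#'
#' @param image a [phantom_image]
#' @param edge_segment one entry of `roi_set$edge_segments`
#' @param angle_deg slant angle from [estimate_edge_angle()]
#' @param band_halfwidth_px half-width of the projection band, native px
#' @param bin_px ESF bin pitch in native pixels
#' @return object of class `esf_profile`
#' @export
build_oversampled_esf <- function(image, edge_segment, angle_deg,
                                  band_halfwidth_px = 32, bin_px = 0.1) {
  px <- image$pixels
  seg <- edge_segment
  vertical <- seg$orientation == "vertical"
  th <- angle_deg * pi / 180
  # line slope in (t, x) coordinates implied by the square rotation
  slope <- if (vertical) -tan(th) else tan(th)
  cr <- edge_crossings(image, seg)
  intercept <- mean(cr$crossing - slope * cr$t)
  ts <- seq(min(cr$t), max(cr$t))
  x_line <- intercept + slope * ts
  W <- ceiling(band_halfwidth_px)
  lim <- if (vertical) ncol(px) else nrow(px)
  if (any(x_line - W < 1) || any(x_line + W > lim))
    stop("ESF band clipped by the image border; move the edge or narrow the band")
  dist <- numeric(0); val <- numeric(0)
  offs <- -W:W
  cth <- cos(th)
  for (k in seq_along(ts)) {
    xs <- round(x_line[k]) + offs
    v <- if (vertical) px[ts[k], xs] else px[xs, ts[k]]
    dist <- c(dist, (xs - x_line[k]) * cth)
    val <- c(val, v)
  }
  bins <- round(dist / bin_px)
  b1 <- min(bins); b2 <- max(bins)
  sums <- tapply(val, factor(bins, levels = b1:b2), mean)
  centers <- (b1:b2) * bin_px
  values <- as.numeric(sums)
  if (anyNA(values)) {
    ok <- !is.na(values)
    values <- stats::approx(centers[ok], values[ok], xout = centers, rule = 2)$y
  }
  q <- length(values) %/% 4
  if (mean(values[1:q]) > mean(values[(length(values) - q + 1):length(values)])) {
    values <- rev(values)
  }
  structure(list(dist_px = centers, values = values, bin_px = bin_px,
                 pixel_spacing_mm = image$pixel_spacing_mm[1],
                 direction = seg$direction, angle_deg = angle_deg),
            class = "esf_profile")
}

#' Compute the presampled MTF from an oversampled ESF
#'
#' @param esf an `esf_profile` from [build_oversampled_esf()]
#' @param grid_n transform length of the common frequency grid
#' @return object of class `mtf_curve` with `frequencies` (cycles/mm, 0 to
#'   Nyquist on the common grid), `values` (1 at zero frequency),
#'   `direction`, `edge_angle_deg`
#' @export
compute_presampled_mtf <- function(esf, grid_n = 256L) {
  v <- esf$values
  n <- length(v)
  span_px <- diff(range(esf$dist_px))
  if (span_px < 64)
    stop("ESF spans ", round(span_px), " native pixels; >= 64 required")
  q <- n %/% 4
  contrast <- mean(v[(n - q + 1):n]) - mean(v[1:q])
  if (!is.finite(contrast) || contrast <= 0)
    stop("zero-contrast edge: no edge signal in the ESF")
  lsf <- c(0, (v[3:n] - v[1:(n - 2)]) / 2, 0)
  peak <- which.max(abs(lsf))
  # Tukey taper centered on the LSF peak: flat over the central half of the
  # profile, cosine roll-off outside. A full Hann attenuates the LSF core
  # when the spread is a large fraction of the band and biases the MTF high.
  L <- max(peak - 1L, n - peak)
  d <- abs(seq_len(n) - peak)
  w <- ifelse(d <= L / 2, 1, 0.5 * (1 + cos(pi * (d - L / 2) / (L / 2))))
  lsf <- lsf * w
  # zero-pad so the fine frequency sampling is at least ~3x the common grid
  np <- 2^ceiling(log2(max(n, 2 * grid_n / esf$bin_px)))
  lsf <- c(lsf, rep(0, np - n))
  sp <- abs(stats::fft(lsf))
  if (sp[1] <= 0) stop("zero-contrast edge: no edge signal in the ESF")
  mtf_fine <- sp / sp[1]
  delta <- esf$bin_px * esf$pixel_spacing_mm      # supersampled pitch, mm
  freq_fine <- (seq_len(np) - 1) / (np * delta)
  ny <- 1 / (2 * esf$pixel_spacing_mm)
  keep <- freq_fine <= ny * 1.0000001
  freq_fine <- freq_fine[keep]; mtf_fine <- mtf_fine[keep]

  grid <- common_frequency_grid(esf$pixel_spacing_mm, grid_n)
  du <- grid[2] - grid[1]
  idx <- round(freq_fine / du) + 1L
  idx[idx > length(grid)] <- length(grid)
  values <- as.numeric(tapply(mtf_fine, factor(idx, levels = seq_along(grid)), mean))
  if (anyNA(values)) {
    ok <- !is.na(values)
    values <- stats::approx(grid[ok], values[ok], xout = grid, rule = 2)$y
  }
  values <- values / values[1]
  structure(list(frequencies = grid, values = values,
                 direction = esf$direction, edge_angle_deg = esf$angle_deg,
                 pixel_spacing_mm = esf$pixel_spacing_mm,
                 warnings = character()),
            class = "mtf_curve")
}

#' Characteristic frequencies where the MTF crosses 50%, 20% and 10%
#'
#' First downward crossing of each level, linearly interpolated between the
#' bracketing samples; `NA` when the level is not crossed below Nyquist.
#'
#' @param mtf an `mtf_curve`
#' @return list of class `characteristic_frequencies`: `f50`, `f20`, `f10`
#'   in cycles/mm
#' @export
characteristic_frequencies <- function(mtf) {
  cross <- function(level) {
    v <- mtf$values; u <- mtf$frequencies
    i <- which(v[-length(v)] >= level & v[-1] < level)
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    u[i] + (v[i] - level) / (v[i] - v[i + 1]) * (u[i + 1] - u[i])
  }
  structure(list(f50 = cross(0.5), f20 = cross(0.2), f10 = cross(0.1)),
            class = "characteristic_frequencies")
}

#' Average two directional MTF curves
#' @param mtf_h,mtf_v horizontal and vertical `mtf_curve`s on one grid
#' @return an `mtf_curve` with `direction = "averaged"`
#' @export
average_mtf <- function(mtf_h, mtf_v) {
  stopifnot(isTRUE(all.equal(mtf_h$frequencies, mtf_v$frequencies)))
  out <- mtf_h
  out$values <- (mtf_h$values + mtf_v$values) / 2
  out$direction <- "averaged"
  out$edge_angle_deg <- mean(c(mtf_h$edge_angle_deg, mtf_v$edge_angle_deg))
  out$warnings <- union(mtf_h$warnings, mtf_v$warnings)
  out
}

#' Put an MTF and an NNPS curve on the common frequency grid
#'
#' The NNPS grid is the common grid; the MTF is linearly interpolated onto
#' it (exact where the grids already coincide).
#'
#' @param mtf an `mtf_curve`
#' @param nnps an `nnps_curve`
#' @return list with elements `mtf` and `nnps` sharing `frequencies`
#' @export
common_grid <- function(mtf, nnps) {
  out <- mtf
  out$values <- interp1(mtf$frequencies, mtf$values, nnps$frequencies)
  out$frequencies <- nnps$frequencies
  list(mtf = out, nnps = nnps)
}

#' Write a frequency curve (MTF or NNPS) as CSV
#' @param curve an `mtf_curve` or `nnps_curve`
#' @param path output file
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(frequency_cycles_per_mm = curve$frequencies,
                              value = curve$values,
                              direction = curve$direction),
                   path, row.names = FALSE)
  invisible(path)
}
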