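# Detrended normalized noise power spectrum.
#
# The homogeneous region (512 x 512 px, or 256 x 256 on small detectors) is
# flattened by fitting and subtracting a least-squares linear ramp along
# each orthogonal direction in turn, then tiled into 3 x 3 half-overlapping
# ROIs of half the region size. Per ROI the mean is removed and
#   NPS(u,v) = (p_x p_y / (N_x N_y)) * < |DFT(ROI)|^2 >
# is averaged over the 9 ROIs; NNPS = NPS / (large-area mean)^2 (units
# mm^2). 1-D directional cuts average the 3 lines on each side of (but
# excluding) the zero-frequency axes; a radial average over all of 2-D
# frequency space (excluding only the DC bin) is also provided.

#' Remove a planar gradient from a homogeneous region
#'
#' Fits and subtracts a least-squares linear ramp along rows, then along
#' columns, and restores the original mean (detrending removes the
#' gradient, not the level).
#'
#' @param region numeric matrix (>= 256 x 256 for NNPS use)
#' @return detrended matrix with unchanged mean
#' @export
detrend_region <- function(region) {
  m0 <- mean(region)
  nc <- ncol(region); nr <- nrow(region)
  cx <- seq_len(nc) - (nc + 1) / 2
  col_means <- colMeans(region)
  beta_c <- sum(cx * (col_means - mean(col_means))) / sum(cx^2)
  region <- region - matrix(beta_c * cx, nr, nc, byrow = TRUE)
  rx <- seq_len(nr) - (nr + 1) / 2
  row_means <- rowMeans(region)
  beta_r <- sum(rx * (row_means - mean(row_means))) / sum(rx^2)
  region <- region - matrix(beta_r * rx, nr, nc)
  region - mean(region) + m0
}

#' Compute the detrended NNPS of a homogeneous region
#'
#' @param region numeric matrix, 512 x 512 (or 256 x 256 fallback); ROI size
#'   is half the region size, offsets at 0/50/100% (3 x 3 half-overlapping)
#' @param pixel_spacing_mm pixel pitch, mm
#' @param detrend remove the planar gradient first (default TRUE)
#' @param directions which 1-D curves to return; the first is the primary
#' @return object of class `nnps_curve`: `frequencies` (common grid, 0 to
#'   Nyquist), `values` (mm^2) for the primary direction, `cuts` (named list
#'   of all requested 1-D curves), `nnps2d` (full 2-D NNPS, DC at [1,1]),
#'   `large_area_mean`, `large_area_variance`
#' @export
compute_nnps <- function(region, pixel_spacing_mm, detrend = TRUE,
                         directions = c("radial", "horizontal", "vertical")) {
  nr <- nrow(region); nc <- ncol(region)
  if (nr < 256 || nc < 256)
    stop("NNPS region must be at least 256 x 256 pixels")
  if (nr != nc) stop("NNPS region must be square")
  large_mean <- mean(region)
  if (large_mean <= 0) stop("NNPS undefined: region mean <= 0")
  if (detrend) region <- detrend_region(region)
  large_var <- stats::var(as.vector(region))

  N <- nr %/% 2L
  p <- pixel_spacing_mm
  offs <- c(0L, N %/% 2L, N)
  acc <- matrix(0, N, N)
  for (ro in offs) for (co in offs) {
    roi <- region[(ro + 1):(ro + N), (co + 1):(co + N)]
    roi <- roi - mean(roi)
    acc <- acc + Mod(stats::fft(roi))^2
  }
  nps2d <- (p * p / (N * N)) * acc / 9
  nnps2d <- nps2d / large_mean^2

  ny <- 1 / (2 * p)
  grid <- common_frequency_grid(p, N)
  half <- N %/% 2L

  # signed frequency index helper: k in 0..N-1 -> frequency k/(N p), alias
  fold <- function(v) {
    # average +u and -u bins onto 0..Nyquist
    out <- numeric(half + 1L)
    out[1] <- v[1]
    out[half + 1L] <- v[half + 1L]
    ks <- 2:half
    out[ks] <- (v[ks] + v[N + 2L - ks]) / 2
    out
  }
  axis_lines <- c(2:4, N - (0:2))  # the 3 lines each side of the axis
  cuts <- list()
  for (dirn in directions) {
    vals <- switch(dirn,
      horizontal = fold(colMeans(nnps2d[axis_lines, , drop = FALSE])),
      vertical   = fold(rowMeans(nnps2d[, axis_lines, drop = FALSE])),
      radial = {
        k <- c(0:(N - 1))
        k[k > N / 2] <- k[k > N / 2] - N
        fr <- abs(k) / (N * p)
        R <- sqrt(outer(fr^2, fr^2, "+"))
        df <- grid[2] - grid[1]
        bin <- round(R / df) + 1L
        bin[R > ny + df / 2] <- NA  # corners beyond Nyquist
        bin[1, 1] <- NA             # exclude DC
        vals <- as.numeric(tapply(as.vector(nnps2d),
                                  factor(as.vector(bin), levels = seq_len(half + 1L)),
                                  mean))
        if (anyNA(vals)) {  # e.g. the DC-only bin at u = 0
          ok <- !is.na(vals)
          vals <- stats::approx(grid[ok], vals[ok], xout = grid, rule = 2)$y
        }
        vals
      },
      stop("unknown NNPS direction: ", dirn))
    cuts[[dirn]] <- vals
  }
  primary <- directions[1]
  structure(list(frequencies = grid, values = cuts[[primary]],
                 direction = primary, cuts = cuts, nnps2d = nnps2d,
                 pixel_spacing_mm = p,
                 large_area_mean = large_mean, large_area_variance = large_var),
            class = "nnps_curve")
}

#' Integral of the 2-D NNPS (Parseval check)
#'
#' For trend-free noise, `sum(NNPS) * df_u * df_v` recovers
#' `variance / mean^2` of the region.
#'
#' @param nnps an `nnps_curve`
#' @return the 2-D integral (unitless relative variance)
#' @export
nnps_parseval_sum <- function(nnps) {
  N <- nrow(nnps$nnps2d)
  df <- 1 / (N * nnps$pixel_spacing_mm)
  sum(nnps$nnps2d) * df * df
}
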