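# NPWE detectability index d'.
#
# Task-based figure of merit for detecting a disk of diameter D and nominal
# contrast C on the measured system:
#
#   d' = 2 pi C * I1 / sqrt(I2)
#   I1 = int S^2(u) MTF^2(u) VTF^2(u) u du
#   I2 = int S^2(u) MTF^2(u) VTF^4(u) NNPS(u) u du
#
# with S the Fourier transform of the disk and VTF a band-pass eye filter
# referenced to the viewing distance. Both integrals are evaluated by the
# trapezoid rule on the common frequency grid over [0, Nyquist].

#' Detection task definition
#'
#' Default disk diameters are 0.3 and 4.0 mm for radiography and 0.1 and
#' 0.25 mm for mammography, at a 400 mm viewing distance.
#'
#' @param contrast_C nominal (unitless) contrast of the disk
#' @param disk_diameter_D_mm disk diameter, mm
#' @param viewing_distance_mm eye-to-image distance, mm
#' @export
detection_task <- function(contrast_C, disk_diameter_D_mm,
                           viewing_distance_mm = 400) {
  stopifnot(disk_diameter_D_mm > 0, viewing_distance_mm > 0)
  structure(list(contrast_C = contrast_C,
                 disk_diameter_D_mm = disk_diameter_D_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "detection_task")
}

#' Default disk diameters per modality
#' @param modality `"radiography"` or `"mammography"`
#' @return `c(small, large)` diameters in mm
#' @export
default_disk_diameters <- function(modality) {
  if (modality == "mammography") c(0.1, 0.25) else c(0.3, 4.0)
}

#' Object shape function: Fourier transform of a disk
#'
#' `S(u) = (pi D^2 / 4) * 2 J1(pi D u) / (pi D u)`, with the disk-area
#' limit `S(0) = pi D^2 / 4` by continuity. Units mm^2.
#'
#' @param D_mm disk diameter, mm
#' @param frequencies cycles/mm
#' @export
disk_shape_function <- function(D_mm, frequencies) {
  stopifnot(D_mm > 0)
  area <- pi * D_mm^2 / 4
  x <- pi * D_mm * frequencies
  ifelse(x == 0, area, area * 2 * besselJ(x, 1) / x)
}

#' Visual transfer function (band-pass eye filter)
#'
#' Spatial frequency u (cycles/mm) is mapped to angular frequency
#' `f = u * distance * pi / 180` (cycles/degree) and filtered with
#' `VTF = f^1.5 exp(-c f)`, `c = 1.5/4` so the response peaks at 4
#' cycles/degree, normalized to a maximum of 1. `VTF(0) = 0`.
#'
#' @param frequencies cycles/mm
#' @param viewing_distance_mm viewing distance, mm
#' @export
visual_transfer_function <- function(frequencies, viewing_distance_mm = 400) {
  stopifnot(viewing_distance_mm > 0)
  f <- frequencies * viewing_distance_mm * pi / 180
  cc <- 1.5 / 4
  v <- f^1.5 * exp(-cc * f)
  peak <- (1.5 / cc)^1.5 * exp(-1.5)   # value at f = 1.5/c = 4 cyc/deg
  v / peak
}

#' NPWE detectability index
#'
#' @param mtf an `mtf_curve` on the common grid (use [common_grid()])
#' @param nnps an `nnps_curve` on the same grid
#' @param task a [detection_task()]
#' @param constant_placement `"as_printed"` evaluates
#'   `2 pi C I1 / sqrt(I2)`; `"radial"` uses the fully radial-integral form
#'   `sqrt((2 pi I1)^2 / (2 pi I2)) C = sqrt(2 pi) C I1 / sqrt(I2)`
#' @return d' (unitless)
#' @export
compute_dprime <- function(mtf, nnps, task,
                           constant_placement = c("as_printed", "radial")) {
  constant_placement <- match.arg(constant_placement)
  u <- nnps$frequencies
  if (!isTRUE(all.equal(mtf$frequencies, u)))
    stop("MTF and NNPS are not on a common frequency grid; call common_grid()")
  S <- disk_shape_function(task$disk_diameter_D_mm, u)
  V <- visual_transfer_function(u, task$viewing_distance_mm)
  M <- mtf$values
  Np <- nnps$values
  if (all(Np == 0)) stop("NNPS identically zero: d' is infinite/undefined")
  trapz <- function(y) sum(diff(u) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  I1 <- trapz(S^2 * M^2 * V^2 * u)
  I2 <- trapz(S^2 * M^2 * V^4 * Np * u)
  if (I2 <= 0) stop("noise integral is zero: d' undefined")
  k <- switch(constant_placement, as_printed = 2 * pi, radial = sqrt(2 * pi))
  k * task$contrast_C * I1 / sqrt(I2)
}
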