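# Synthetic phantom-image simulator.
#
# Emulates an unprocessed ("for processing") flat-field image of the simple
# QC phantom: a uniform attenuator background carrying a high-contrast Cu
# square (slanted 2-5 degrees, used for the slanted-edge MTF) and a small
# low-contrast Al square (used for SDNR), with Gaussian system blur,
# Poisson-plus-Gaussian detector noise, an optional planar signal gradient,
# and injectable detector defects. Every analysis module is validated
# against the analytic ground truth this generator carries.

#' Phantom geometry description
#'
#' Defaults follow the published phantom designs: the radiographic target
#' plate is 28 x 28 cm PMMA with a 5 x 5 cm copper square (slanted, for MTF)
#' and a 1 x 1 cm aluminium square (for SDNR); the mammographic plate is
#' 24 x 30 cm with the same lateral layout (the Cu and Al squares are
#' thinner, which shows up as different default transmissions in
#' [simulation_config()], not in the geometry).
#'
#' @param modality `"radiography"` or `"mammography"`
#' @param plate_size_mm plate extent in mm, `c(height, width)`
#' @param cu_square_side_mm,al_square_side_mm target side lengths in mm
#' @param cu_edge_angle_deg slant of the Cu square relative to the pixel
#'   rows, degrees (clockwise positive); 2-5 degrees for valid MTF analysis
#' @param cu_center_frac,al_center_frac fractional positions `c(row, col)`
#'   of the target centers on the imaged plate
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(modality = c("radiography", "mammography"),
                         plate_size_mm = NULL,
                         cu_square_side_mm = 50,
                         al_square_side_mm = 10,
                         cu_edge_angle_deg = 3,
                         cu_center_frac = c(0.30, 0.5),
                         al_center_frac = c(0.30, 0.15)) {
  modality <- match.arg(modality)
  if (is.null(plate_size_mm))
    plate_size_mm <- if (modality == "radiography") c(280, 280) else c(300, 240)
  for (f in c("cu_square_side_mm", "al_square_side_mm"))
    if (!is_scalar_number(get(f)) || get(f) <= 0)
      stop("phantom_spec: ", f, " must be a positive number")
  if (!is_scalar_number(cu_edge_angle_deg))
    stop("phantom_spec: cu_edge_angle_deg must be a number")
  if (abs(cu_edge_angle_deg) < 2 || abs(cu_edge_angle_deg) > 5)
    warning("cu_edge_angle_deg outside the recommended 2-5 degree range; ",
            "MTF estimates may be unreliable")
  structure(list(modality = modality, plate_size_mm = plate_size_mm,
                 cu_square_side_mm = cu_square_side_mm,
                 al_square_side_mm = al_square_side_mm,
                 cu_edge_angle_deg = cu_edge_angle_deg,
                 cu_center_frac = cu_center_frac,
                 al_center_frac = al_center_frac),
            class = "phantom_spec")
}

#' Detector defect to inject into a simulated image
#'
#' @param kind `"dead_pixel"`, `"dead_row"`, `"dead_column"` or `"blob"`
#' @param location_px pixel coordinates `c(row, col)` (for dead_row /
#'   dead_column only the relevant coordinate is used)
#' @param magnitude replacement value in detector units for dead elements
#'   (default 0), or additive amplitude for `"blob"`
#' @param sigma_px Gaussian radius of a `"blob"`, pixels
#' @export
artifact_spec <- function(kind = c("dead_pixel", "dead_row", "dead_column", "blob"),
                          location_px, magnitude = 0, sigma_px = 3) {
  kind <- match.arg(kind)
  structure(list(kind = kind, location_px = round(location_px),
                 magnitude = magnitude, sigma_px = sigma_px),
            class = "artifact_spec")
}

#' Acquisition metadata carried in the image header
#'
#' Absent values are `NA`, never zero.
#' @param kvp tube voltage, kV
#' @param tube_load_mas tube load, mAs
#' @param exposure_index vendor exposure index
#' @param organ_dose,entrance_dose dose values (mGy) or `NA`
#' @param anode_filter anode/filter combination, free text
#' @param detector_id,station_name identifiers
#' @param acquisition_datetime `POSIXct` timestamp
#' @export
acquisition_metadata <- function(kvp = NA_real_, tube_load_mas = NA_real_,
                                 exposure_index = NA_real_,
                                 organ_dose = NA_real_, entrance_dose = NA_real_,
                                 anode_filter = NA_character_,
                                 detector_id = NA_character_,
                                 station_name = NA_character_,
                                 acquisition_datetime = as.POSIXct(NA)) {
  if (!is.na(kvp) && kvp <= 0) stop("kvp must be > 0 when present")
  structure(list(kvp = kvp, tube_load_mas = tube_load_mas,
                 exposure_index = exposure_index, organ_dose = organ_dose,
                 entrance_dose = entrance_dose, anode_filter = anode_filter,
                 detector_id = detector_id, station_name = station_name,
                 acquisition_datetime = acquisition_datetime),
            class = "acquisition_metadata")
}

#' Full simulation configuration
#'
#' The defaults describe a plausible flat-field acquisition: mean background
#' around 10^4 detector units, quantum-limited noise (`poisson_gain = 1`)
#' plus a small electronic floor, and 0.2 mm of Gaussian system blur. Cu /
#' Al transmissions default to 0.5 / 0.9 for radiography (2 mm Cu and 4 mm
#' Al targets behind a hardened 80 kVp beam) and 0.25 / 0.85 for mammography
#' (1 mm Cu, 0.2 mm Al at 28 kVp).
#'
#' @param spec a [phantom_spec()]
#' @param pixel_spacing_mm detector pitch, mm
#' @param image_size_px image size `c(rows, cols)`; the image is assumed
#'   collimated to the plate, so fractional target positions map onto it
#' @param mean_background_signal mean background level, detector units
#' @param cu_transmission,al_transmission target transmission factors (0, 1]
#' @param blur_sigma_mm Gaussian system blur, mm (>= 0)
#' @param poisson_gain detector units per quantum (0 disables Poisson noise)
#' @param electronic_noise_sd Gaussian read-noise SD, detector units
#' @param gradient_slope planar gradient `c(per_row_mm, per_col_mm)` in
#'   detector units per mm, applied as a zero-mean centered ramp
#' @param artifacts list of [artifact_spec()]s
#' @param seed integer RNG seed: identical config + seed gives a
#'   bit-identical image
#' @param metadata an [acquisition_metadata()]; defaults per modality
#' @export
simulation_config <- function(spec = phantom_spec(),
                              pixel_spacing_mm = 0.2,
                              image_size_px = c(1024, 1024),
                              mean_background_signal = 10000,
                              cu_transmission = NULL,
                              al_transmission = NULL,
                              blur_sigma_mm = 0.2,
                              poisson_gain = 1,
                              electronic_noise_sd = 20,
                              gradient_slope = c(0, 0),
                              artifacts = list(),
                              seed = 1L,
                              metadata = NULL) {
  if (is.null(cu_transmission))
    cu_transmission <- if (spec$modality == "radiography") 0.5 else 0.25
  if (is.null(al_transmission))
    al_transmission <- if (spec$modality == "radiography") 0.9 else 0.85
  if (is.null(metadata)) {
    metadata <- if (spec$modality == "radiography") {
      acquisition_metadata(kvp = 80, tube_load_mas = 10,
                           exposure_index = round(mean_background_signal / 25),
                           anode_filter = "W/none", detector_id = "SIM-DR-1",
                           station_name = "SIM",
                           acquisition_datetime = as.POSIXct("2021-06-01 08:00:00", tz = "UTC"))
    } else {
      acquisition_metadata(kvp = 28, tube_load_mas = 80,
                           exposure_index = round(mean_background_signal / 25),
                           anode_filter = "W/Rh", detector_id = "SIM-MG-1",
                           station_name = "SIM",
                           acquisition_datetime = as.POSIXct("2021-06-01 08:00:00", tz = "UTC"))
    }
  }
  cfg <- structure(list(spec = spec, pixel_spacing_mm = pixel_spacing_mm,
                        image_size_px = as.integer(round(image_size_px)),
                        mean_background_signal = mean_background_signal,
                        cu_transmission = cu_transmission,
                        al_transmission = al_transmission,
                        blur_sigma_mm = blur_sigma_mm,
                        poisson_gain = poisson_gain,
                        electronic_noise_sd = electronic_noise_sd,
                        gradient_slope = gradient_slope,
                        artifacts = artifacts, seed = as.integer(seed),
                        metadata = metadata),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$mean_background_signal <= 0)
    stop("simulation_config: mean_background_signal must be > 0")
  for (f in c("cu_transmission", "al_transmission")) {
    v <- cfg[[f]]
    if (!is_scalar_number(v) || v <= 0 || v > 1)
      stop("simulation_config: ", f, " must be in (0, 1]")
  }
  for (f in c("blur_sigma_mm", "poisson_gain", "electronic_noise_sd"))
    if (cfg[[f]] < 0) stop("simulation_config: ", f, " must be >= 0")
  if (cfg$pixel_spacing_mm <= 0)
    stop("simulation_config: pixel_spacing_mm must be > 0")
  geo <- sim_geometry(cfg)
  dim <- cfg$image_size_px
  for (tgt in c("cu", "al")) {
    g <- geo[[tgt]]
    half <- g$side_px / 2 * 1.1   # slack for the slant
    if (g$center_px[1] - half < 1 || g$center_px[1] + half > dim[1] ||
        g$center_px[2] - half < 1 || g$center_px[2] + half > dim[2])
      stop("simulation_config: ", tgt,
           "_center_frac places the target outside the plate/image")
  }
  for (a in cfg$artifacts) {
    if (any(a$location_px < 1) || a$location_px[1] > dim[1] ||
        a$location_px[2] > dim[2])
      stop("simulation_config: artifact location_px outside the image")
  }
  invisible(cfg)
}

# Target geometry in pixel coordinates
sim_geometry <- function(cfg) {
  dim <- cfg$image_size_px; sp <- cfg$spec; p <- cfg$pixel_spacing_mm
  list(cu = list(center_px = sp$cu_center_frac * dim,
                 side_px = sp$cu_square_side_mm / p,
                 angle_deg = sp$cu_edge_angle_deg),
       al = list(center_px = sp$al_center_frac * dim,
                 side_px = sp$al_square_side_mm / p,
                 angle_deg = 0))
}

# Area-weighted coverage of a rotated square over the pixel grid.
# Interior/exterior pixels are decided analytically; only pixels within
# ~1.5 px of the boundary are supersampled 8 x 8 (box average), so the
# slanted edge is rendered without aliasing at modest cost.
square_coverage <- function(dim, center_px, side_px, angle_deg, ss = 8L) {
  th <- angle_deg * pi / 180
  half <- side_px / 2
  bb_half <- ceiling(half * (abs(cos(th)) + abs(sin(th))) + 2)
  r1 <- max(1L, floor(center_px[1] - bb_half)); r2 <- min(dim[1], ceiling(center_px[1] + bb_half))
  c1 <- max(1L, floor(center_px[2] - bb_half)); c2 <- min(dim[2], ceiling(center_px[2] + bb_half))
  rows <- r1:r2; cols <- c1:c2
  dy <- rows - center_px[1]
  dx <- cols - center_px[2]
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  DY <- matrix(dy, length(rows), length(cols))
  Xp <-  DX * cos(th) + DY * sin(th)
  Yp <- -DX * sin(th) + DY * cos(th)
  d <- pmax(abs(Xp), abs(Yp)) - half
  cov <- matrix(0, length(rows), length(cols))
  cov[d <= -1.5] <- 1
  edge <- which(abs(d) < 1.5, arr.ind = TRUE)
  if (nrow(edge)) {
    off <- ((seq_len(ss) - 0.5) / ss) - 0.5
    sub <- expand.grid(oy = off, ox = off)
    ex <- DX[edge]; ey <- DY[edge]
    acc <- numeric(nrow(edge))
    for (k in seq_len(nrow(sub))) {
      sx <- ex + sub$ox[k]; sy <- ey + sub$oy[k]
      xp <-  sx * cos(th) + sy * sin(th)
      yp <- -sx * sin(th) + sy * cos(th)
      acc <- acc + (pmax(abs(xp), abs(yp)) <= half)
    }
    cov[edge] <- acc / nrow(sub)
  }
  list(rows = rows, cols = cols, cov = cov)
}

#' Analytic signal-difference-to-noise ratio of a simulation configuration
#'
#' The oracle the measured SDNR is validated against:
#' `(M - M * al_transmission) / sqrt(gain * M + electronic_noise_sd^2)`
#' with `M = mean_background_signal`.
#'
#' @param config a [simulation_config()]
#' @return expected SDNR (unitless)
#' @export
expected_sdnr <- function(config) {
  M <- config$mean_background_signal
  v <- config$poisson_gain * M + config$electronic_noise_sd^2
  if (v <= 0) stop("expected_sdnr undefined: all noise sources are zero")
  (M - M * config$al_transmission) / sqrt(v)
}

# Flat NNPS level (mm^2) of the white-noise model at the background level
expected_nnps_level <- function(config) {
  M <- config$mean_background_signal
  v <- config$poisson_gain * M + config$electronic_noise_sd^2
  v * config$pixel_spacing_mm^2 / M^2
}

#' Simulate a phantom image with analytic ground truth
#'
#' Rendering order: area-weighted target rendering, Gaussian system blur,
#' additive centered planar gradient, Poisson noise (`gain * Pois(x/gain)`),
#' additive Gaussian electronic noise, artifact overwrite, rounding to
#' 16-bit integers. A value outside \[0, 65535\] is an error (clipping is
#' never silent).
#'
#' @param config a [simulation_config()]
#' @return list with `image` (a [phantom_image]) and `truth`, the ground
#'   truth: `analytic_mtf(u)` (Gaussian times pixel-aperture sinc),
#'   `expected_sdnr`, `expected_nnps_level` (mm^2) and `roi_truth` (a
#'   `roi_set` built from the true geometry)
#' @export
simulate_phantom_image <- function(config) {
  validate_simulation_config(config)
  dim <- config$image_size_px; p <- config$pixel_spacing_mm
  M <- config$mean_background_signal
  geo <- sim_geometry(config)

  scene <- matrix(M, dim[1], dim[2])
  cu <- square_coverage(dim, geo$cu$center_px, geo$cu$side_px, geo$cu$angle_deg)
  scene[cu$rows, cu$cols] <- scene[cu$rows, cu$cols] -
    M * (1 - config$cu_transmission) * cu$cov
  al <- square_coverage(dim, geo$al$center_px, geo$al$side_px, 0)
  scene[al$rows, al$cols] <- scene[al$rows, al$cols] -
    M * (1 - config$al_transmission) * al$cov

  scene <- blur_gaussian(scene, config$blur_sigma_mm / p)

  if (any(config$gradient_slope != 0)) {
    rmm <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * p
    cmm <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * p
    scene <- scene + outer(rmm * config$gradient_slope[1], rep(1, dim[2])) +
      outer(rep(1, dim[1]), cmm * config$gradient_slope[2])
  }

  pixels <- with_seed(config$seed, {
    x <- scene
    g <- config$poisson_gain
    if (g > 0) x <- g * matrix(stats::rpois(length(x), as.vector(x) / g), dim[1], dim[2])
    if (config$electronic_noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = config$electronic_noise_sd),
                      dim[1], dim[2])
    x
  })

  for (a in config$artifacts) pixels <- apply_artifact(pixels, a)

  pixels <- round(pixels)
  if (any(pixels < 0) || any(pixels > 65535))
    stop("simulated signal clips the 16-bit range; lower ",
         "mean_background_signal or the noise/artifact magnitudes")

  img <- new_phantom_image(pixels, c(p, p), config$spec$modality,
                           "for_processing", config$metadata)

  sigma <- config$blur_sigma_mm
  analytic_mtf <- function(u) {
    ap <- ifelse(u == 0, 1, abs(sin(pi * p * u) / (pi * p * u)))
    exp(-2 * pi^2 * sigma^2 * u^2) * ap
  }
  truth <- list(
    analytic_mtf = analytic_mtf,
    blur_sigma_mm = sigma,
    expected_sdnr = if (config$poisson_gain > 0 || config$electronic_noise_sd > 0)
      expected_sdnr(config) else NA_real_,
    expected_nnps_level = expected_nnps_level(config),
    expected_variance = config$poisson_gain * M + config$electronic_noise_sd^2,
    roi_truth = build_roi_set(dim, p, geo$cu$center_px, geo$cu$side_px,
                              geo$cu$angle_deg, geo$al$center_px, geo$al$side_px,
                              require_nnps = FALSE))
  list(image = img, truth = truth)
}

apply_artifact <- function(pixels, a) {
  r <- a$location_px[1]; cc <- a$location_px[2]
  switch(a$kind,
    dead_pixel  = { pixels[r, cc] <- a$magnitude; pixels },
    dead_row    = { pixels[r, ]  <- a$magnitude; pixels },
    dead_column = { pixels[, cc] <- a$magnitude; pixels },
    blob = {
      half <- ceiling(3 * a$sigma_px)
      rows <- max(1, r - half):min(nrow(pixels), r + half)
      cols <- max(1, cc - half):min(ncol(pixels), cc + half)
      d2 <- outer((rows - r)^2, (cols - cc)^2, "+")
      pixels[rows, cols] <- pixels[rows, cols] +
        a$magnitude * exp(-d2 / (2 * a$sigma_px^2))
      pixels
    })
}

#' Write simulator ground truth as a plain-text key/value sidecar
#'
#' @param truth the `truth` element returned by [simulate_phantom_image()]
#' @param path output file
#' @export
write_ground_truth <- function(truth, path) {
  rt <- truth$roi_truth
  lines <- c(
    sprintf("blur_sigma_mm=%.10g", truth$blur_sigma_mm),
    sprintf("expected_sdnr=%.10g", truth$expected_sdnr),
    sprintf("expected_nnps_level=%.10g", truth$expected_nnps_level),
    sprintf("expected_variance=%.10g", truth$expected_variance),
    sprintf("cu_center_px=%.4f,%.4f", rt$cu_square$center_px[1], rt$cu_square$center_px[2]),
    sprintf("cu_side_px=%.4f", rt$cu_square$side_px),
    sprintf("cu_angle_deg=%.4f", rt$cu_square$angle_deg),
    sprintf("al_center_px=%.4f,%.4f", rt$al_square$center_px[1], rt$al_square$center_px[2]))
  writeLines(lines, path)
  invisible(path)
}
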