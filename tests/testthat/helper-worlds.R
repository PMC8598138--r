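# Shared desk-scale simulation worlds. Geometry is shrunk relative to the
# physical phantom so tests stay fast; physical parameters (background
# level, noise model, pitch) follow the package defaults.

# Edge world: a 35 mm Cu square centered in a 51 mm field at 0.1 mm pitch;
# noiseless by default (for MTF oracle comparisons).
edge_spec <- function(angle = 3) {
  suppressWarnings(phantom_spec(cu_square_side_mm = 35, al_square_side_mm = 4,
                                cu_edge_angle_deg = angle,
                                cu_center_frac = c(0.5, 0.5),
                                al_center_frac = c(0.06, 0.10)))
}

edge_config <- function(sigma = 0.5, angle = 3, seed = 1, noise = FALSE, ...) {
  simulation_config(spec = edge_spec(angle), pixel_spacing_mm = 0.1,
                    image_size_px = c(512, 512), blur_sigma_mm = sigma,
                    poisson_gain = if (noise) 1 else 0,
                    electronic_noise_sd = if (noise) 20 else 0,
                    seed = seed, ...)
}

# SDNR world: small 51 mm field at 0.2 mm pitch with both targets; fast
# enough for Monte-Carlo loops.
sdnr_spec <- phantom_spec(cu_square_side_mm = 20, al_square_side_mm = 10,
                          cu_center_frac = c(0.35, 0.5),
                          al_center_frac = c(0.75, 0.25))

sdnr_config <- function(seed = 1, M = 10000, ...) {
  simulation_config(spec = sdnr_spec, pixel_spacing_mm = 0.2,
                    image_size_px = c(256, 256),
                    mean_background_signal = M, seed = seed, ...)
}

# Uniform world: targets present but fully transparent -> flat-field image.
uniform_spec <- phantom_spec(cu_square_side_mm = 4, al_square_side_mm = 2,
                             cu_center_frac = c(0.25, 0.25),
                             al_center_frac = c(0.7, 0.7))

uniform_config <- function(seed = 1, size = 512, p = 0.1, M = 10000,
                           gain = 1, sd = 20, blur = 0, ...) {
  simulation_config(spec = uniform_spec, pixel_spacing_mm = p,
                    image_size_px = c(size, size), mean_background_signal = M,
                    cu_transmission = 1, al_transmission = 1,
                    blur_sigma_mm = blur, poisson_gain = gain,
                    electronic_noise_sd = sd, seed = seed, ...)
}

# Hand-built frequency curves for detectability tests.
make_mtf_curve <- function(frequencies, values, p = 0.1) {
  structure(list(frequencies = frequencies, values = values,
                 direction = "averaged", edge_angle_deg = 3,
                 pixel_spacing_mm = p, warnings = character()),
            class = "mtf_curve")
}

make_nnps_curve <- function(frequencies, values, p = 0.1) {
  structure(list(frequencies = frequencies, values = values,
                 direction = "radial", cuts = list(radial = values),
                 nnps2d = NULL, pixel_spacing_mm = p,
                 large_area_mean = 10000, large_area_variance = 10000),
            class = "nnps_curve")
}

# A deterministic full-size phantom world for pipeline tests (slow-ish:
# ~2 s to simulate); memoised per session.
.pipeline_cache <- new.env()
pipeline_sim <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.pipeline_cache[[key]]))
    .pipeline_cache[[key]] <- simulate_phantom_image(simulation_config(seed = seed))
  .pipeline_cache[[key]]
}

make_records <- function(values, metric = "sdnr", device = "dev-1") {
  lapply(seq_along(values), function(i) {
    args <- list(device_key = device,
                 acquisition_datetime = as.POSIXct("2021-01-01", tz = "UTC") +
                   i * 86400)
    args[[metric]] <- values[i]
    do.call(qc_record, args)
  })
}
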