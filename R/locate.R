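# Automatic ROI localization.
#
# The Cu square is segmented by Otsu thresholding of the plate-interior
# histogram and taken as the connected component whose area best matches
# the expected square size (ties broken by proximity to the expected
# fractional position); its slant angle is then refined by subpixel edge
# regression. The Al square is the strongest dark window of its expected
# size (integral-image matched filter) outside the Cu region. The NNPS
# region is placed greedily at maximal clearance from both targets.

localization_error <- function(msg) {
  stop(structure(class = c("phantomqc_localization_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Automatically locate the analysis ROIs in a phantom image
#'
#' @param image a [phantom_image]
#' @param spec the [phantom_spec()] describing the expected targets
#' @return a `roi_set`; fails with a `phantomqc_localization_error` when no
#'   candidate satisfies the size/contrast bounds (signalling manual
#'   placement via [override_rois()])
#' @export
locate_rois <- function(image, spec) {
  px <- image$pixels
  p <- image$pixel_spacing_mm[1]
  dim <- dim(px)
  if (spec$modality != image$modality)
    warning("phantom spec modality (", spec$modality,
            ") does not match the image (", image$modality, ")")

  cu_side_px <- spec$cu_square_side_mm / p
  al_side_px <- spec$al_square_side_mm / p
  cu_area <- cu_side_px^2

  # --- Cu square: Otsu + connected components -----------------------------
  inset <- round(dim * 0.02)
  interior <- px[(1 + inset[1]):(dim[1] - inset[1]),
                 (1 + inset[2]):(dim[2] - inset[2])]
  thr <- otsu_threshold(as.vector(interior))
  mask <- px < thr
  frac <- mean(mask)
  if (frac > 0.35 || frac < 0.25 * cu_area / prod(dim))
    localization_error(
      "no high-contrast target found (threshold segments an implausible area)")
  comps <- tryCatch(mask_components(mask),
                    error = function(e) localization_error(
                      "segmentation too fragmented: no coherent target"))
  areas <- vapply(comps, `[[`, numeric(1), "area")
  ok <- which(areas > 0.5 * cu_area & areas < 2 * cu_area)
  if (length(ok) == 0)
    localization_error("no connected component matches the Cu square size")
  expected_center <- spec$cu_center_frac * dim
  d_exp <- vapply(ok, function(i)
    sum((comps[[i]]$centroid - expected_center)^2), numeric(1))
  cu_comp <- comps[[ok[which.min(d_exp)]]]
  cu_center <- cu_comp$centroid
  side_est <- sqrt(cu_comp$area)

  coarse <- list(center_px = cu_center, side_px = side_est, angle_deg = 0)
  segs <- cu_edge_segments(coarse)
  angle <- tryCatch({
    a_l <- estimate_edge_angle(image, segs$left)
    a_r <- estimate_edge_angle(image, segs$right)
    mean(c(a_l, a_r))
  }, error = function(e)
    localization_error(paste0("Cu edge angle estimation failed: ",
                              conditionMessage(e))))
  warnings <- character()
  if (abs(angle) < 1 || abs(angle) > 7)
    warnings <- c(warnings, sprintf(
      "Cu edge angle %.2f deg outside [1, 7] deg; MTF reliability reduced", angle))

  # --- Al square: darkest window of expected size, Cu region excluded -----
  k <- max(2L, as.integer(round(al_side_px)))
  wm <- window_means(px, k, k)
  cu_box <- cu_bounding_box(list(center_px = cu_center, side_px = side_est,
                                 angle_deg = angle), inflate_px = k)
  block <- matrix(FALSE, nrow(wm), ncol(wm))
  br <- max(1L, cu_box$row1 - k):min(nrow(wm), cu_box$row2)
  bc <- max(1L, cu_box$col1 - k):min(ncol(wm), cu_box$col2)
  block[br, bc] <- TRUE
  edge_excl <- ceiling(0.02 * dim)
  block[seq_len(min(edge_excl[1], nrow(block))), ] <- TRUE
  block[max(1, nrow(block) - edge_excl[1]):nrow(block), ] <- TRUE
  block[, seq_len(min(edge_excl[2], ncol(block)))] <- TRUE
  block[, max(1, ncol(block) - edge_excl[2]):ncol(block)] <- TRUE
  wm_search <- wm
  wm_search[block] <- Inf
  idx <- arrayInd(which.min(wm_search), dim(wm_search))
  al_center <- c(idx[1] + (k - 1) / 2, idx[2] + (k - 1) / 2)
  # contrast significance of the candidate against the local background
  bg_level <- stats::median(px[!mask])
  bg_sd <- stats::mad(px[!mask])
  al_depth <- bg_level - min(wm_search)
  if (!is.finite(al_depth) || al_depth < 5 * bg_sd / k)
    localization_error("no low-contrast Al square candidate above the noise")

  rs <- build_roi_set(dim, p, cu_center, side_est, angle, al_center, al_side_px)
  rs$warnings <- c(rs$warnings, warnings)
  rs
}
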