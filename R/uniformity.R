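# Normalized local-variance map for artifact / nonuniformity detection.
#
# The image is tiled into non-overlapping kernel blocks (2 x 2 mm by
# default, at least 2 px); each block's sample variance is divided by the
# variance of the (detrended) homogeneous NNPS region. Artifact-free noise
# gives values near 1; dead pixels/lines and blobs stand out by an order of
# magnitude and are flagged as connected components above a threshold.

#' Compute the normalized local-variance map
#'
#' @param image a [phantom_image]
#' @param roiset optional `roi_set`; when given, the NNPS region supplies
#'   the normalization variance and blocks overlapping the Cu/Al targets
#'   are masked (`NA`). When `NULL` (uniform attenuator-only image) the
#'   central 256 x 256 px region is used for normalization and nothing is
#'   masked.
#' @param kernel_mm kernel size in mm (default 2)
#' @return object of class `variance_map`: `values` (blocks-grid matrix),
#'   `kernel_px`, `kernel_mm`, `normalization_variance`, `block_origin`
#' @export
compute_variance_map <- function(image, roiset = NULL, kernel_mm = 2) {
  px <- image$pixels
  p <- image$pixel_spacing_mm[1]
  k <- max(2L, as.integer(round(kernel_mm / p)))
  nbr <- nrow(px) %/% k; nbc <- ncol(px) %/% k
  if (nbr < 2 || nbc < 2) stop("image too small for the variance-map kernel")

  norm_region <- if (!is.null(roiset)) {
    extract_roi(px, roiset$nnps_region)
  } else {
    ctr <- dim(px) %/% 2L
    half <- min(128L, min(dim(px)) %/% 2L - 1L)
    px[(ctr[1] - half):(ctr[1] + half - 1L), (ctr[2] - half):(ctr[2] + half - 1L)]
  }
  norm_var <- stats::var(as.vector(detrend_region(norm_region)))
  if (norm_var <= 0)
    stop("normalization variance is zero (constant image); variance map undefined")

  sub <- px[seq_len(nbr * k), seq_len(nbc * k)]
  # per-block sample variance, vectorized over the block grid
  a <- array(sub, dim = c(k, nbr, k, nbc))
  s1 <- apply(a, c(2, 4), sum)
  s2 <- apply(a^2, c(2, 4), sum)
  n <- k * k
  bvar <- (s2 - s1^2 / n) / (n - 1)
  vmap <- bvar / norm_var

  if (!is.null(roiset)) {
    mask_box <- function(b) {
      br <- max(1L, (b$row1 - 1L) %/% k + 1L):min(nbr, (b$row2 - 1L) %/% k + 1L)
      bc <- max(1L, (b$col1 - 1L) %/% k + 1L):min(nbc, (b$col2 - 1L) %/% k + 1L)
      vmap[br, bc] <<- NA
    }
    mask_box(cu_bounding_box(roiset$cu_square, inflate_px = k))
    al_box <- roi_square_mm(roiset$al_square$center_px,
                            roiset$al_square$side_px * p, p)
    mask_box(roi_rect(al_box$row1 - k, al_box$row2 + k,
                      al_box$col1 - k, al_box$col2 + k))
  }
  structure(list(values = vmap, kernel_px = k, kernel_mm = c(k * p, k * p),
                 normalization_variance = norm_var,
                 pixel_spacing_mm = image$pixel_spacing_mm),
            class = "variance_map")
}

#' Flag candidate detector defects on a variance map
#'
#' Connected components (4-connectivity) of blocks above `threshold`,
#' ranked by peak value.
#'
#' @param map a `variance_map`
#' @param threshold normalized-variance threshold (default 5: essentially
#'   impossible under the chi-square null at the block sizes used)
#' @return data frame with one row per defect: `centroid_row_px`,
#'   `centroid_col_px`, `n_blocks`, `peak_value`, `block_rows`, `block_cols`
#' @export
flag_defects <- function(map, threshold = 5) {
  v <- map$values
  mask <- !is.na(v) & v > threshold
  if (!any(mask)) {
    return(data.frame(centroid_row_px = numeric(0), centroid_col_px = numeric(0),
                      n_blocks = integer(0), peak_value = numeric(0),
                      block_rows = character(0), block_cols = character(0),
                      stringsAsFactors = FALSE))
  }
  comps <- mask_components(mask)
  k <- map$kernel_px
  out <- do.call(rbind, lapply(comps, function(cm) {
    rr <- cm$rows; cc <- cm$cols
    peak <- max(v[rr[1]:rr[2], cc[1]:cc[2]][
      mask[rr[1]:rr[2], cc[1]:cc[2]]], na.rm = TRUE)
    data.frame(centroid_row_px = (cm$centroid[1] - 0.5) * k,
               centroid_col_px = (cm$centroid[2] - 0.5) * k,
               n_blocks = cm$area, peak_value = peak,
               block_rows = paste(rr, collapse = ":"),
               block_cols = paste(cc, collapse = ":"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$peak_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match defects between two sessions by centroid proximity
#'
#' Defects whose centroids differ by at most one kernel block are treated
#' as the same (persistent) physical flaw.
#'
#' @param defects_a,defects_b defect tables from [flag_defects()]
#' @param kernel_px kernel size used for both maps
#' @return data frame of matched pairs (`index_a`, `index_b`, `dist_px`)
#' @export
match_defects <- function(defects_a, defects_b, kernel_px) {
  if (nrow(defects_a) == 0 || nrow(defects_b) == 0)
    return(data.frame(index_a = integer(0), index_b = integer(0),
                      dist_px = numeric(0)))
  out <- list()
  for (i in seq_len(nrow(defects_a))) {
    d <- sqrt((defects_b$centroid_row_px - defects_a$centroid_row_px[i])^2 +
                (defects_b$centroid_col_px - defects_a$centroid_col_px[i])^2)
    j <- which.min(d)
    if (d[j] <= kernel_px) {
      out[[length(out) + 1L]] <- data.frame(index_a = i, index_b = j,
                                            dist_px = d[j])
    }
  }
  if (length(out) == 0)
    return(data.frame(index_a = integer(0), index_b = integer(0),
                      dist_px = numeric(0)))
  do.call(rbind, out)
}

#' Render a variance map as a green-to-red PNG
#'
#' Values are clipped to `display_range`; masked blocks render white.
#' Output is deterministic byte-for-byte for fixed input.
#'
#' @param map a `variance_map`
#' @param path output PNG path
#' @param display_range value range mapped to green..red
#' @export
render_variance_map <- function(map, path, display_range = c(0, 5)) {
  stopifnot(all(is.finite(display_range)), diff(display_range) > 0)
  v <- map$values
  x <- pmin(pmax(v, display_range[1]), display_range[2])
  x <- (x - display_range[1]) / diff(display_range)
  ramp <- grDevices::colorRampPalette(c("#00A000", "#C8C800", "#FF0000"))(256)
  grDevices::png(path, width = ncol(v) * 4, height = nrow(v) * 4, type = "cairo")
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(x[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = ramp, zlim = c(0, 1), axes = FALSE, useRaster = TRUE)
  grDevices::dev.off()
  invisible(path)
}
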