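# RoiSet: the located (or ground-truth) analysis regions of a phantom image.
#
# cu_square is an oriented square (center, side, angle in degrees, clockwise
# positive with the origin at the top-left); all other regions are
# axis-aligned `roi_rect`s. Coordinates are 1-based pixels, row-major.

new_roi_set <- function(cu_square, al_square, al_roi, background_roi,
                        nnps_region, edge_segments, warnings = character()) {
  structure(list(cu_square = cu_square, al_square = al_square,
                 al_roi = al_roi, background_roi = background_roi,
                 nnps_region = nnps_region, edge_segments = edge_segments,
                 warnings = warnings),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set>\n  Cu square : center (%.1f, %.1f) px, side %.1f px, angle %.2f deg\n",
              x$cu_square$center_px[1], x$cu_square$center_px[2],
              x$cu_square$side_px, x$cu_square$angle_deg))
  cat(sprintf("  Al square : center (%.1f, %.1f) px\n",
              x$al_square$center_px[1], x$al_square$center_px[2]))
  cat("  Al ROI    : "); print(x$al_roi)
  cat("  Background: "); print(x$background_roi)
  cat("  NNPS      : "); print(x$nnps_region)
  if (length(x$warnings)) cat("  warnings  :", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Axis-aligned bounding box of the oriented Cu square, optionally inflated
cu_bounding_box <- function(cu_square, inflate_px = 0) {
  th <- cu_square$angle_deg * pi / 180
  half <- cu_square$side_px / 2 * (abs(cos(th)) + abs(sin(th))) + inflate_px
  c0 <- cu_square$center_px
  roi_rect(floor(c0[1] - half), ceiling(c0[1] + half),
           floor(c0[2] - half), ceiling(c0[2] + half))
}

# Four edge segments of the oriented Cu square, inset from the corners so
# edge analysis bands avoid corner rounding. Left/right sides are near-
# vertical edges (they measure the horizontal MTF) and vice versa.
cu_edge_segments <- function(cu_square, inset_frac = 0.1) {
  th <- cu_square$angle_deg * pi / 180
  h <- cu_square$side_px / 2
  c0 <- cu_square$center_px
  rot <- function(x, y) c(c0[1] + y * cos(th) + x * sin(th),
                          c0[2] + x * cos(th) - y * sin(th))
  s <- h * (1 - 2 * inset_frac)
  seg <- function(x1, y1, x2, y2, orientation, direction) {
    list(p1 = rot(x1, y1), p2 = rot(x2, y2),
         orientation = orientation, direction = direction)
  }
  list(
    left   = seg(-h, -s, -h,  s, "vertical",   "horizontal"),
    right  = seg( h, -s,  h,  s, "vertical",   "horizontal"),
    top    = seg(-s, -h,  s, -h, "horizontal", "vertical"),
    bottom = seg(-s,  h,  s,  h, "horizontal", "vertical"))
}

# Greedy placement of the homogeneous noise region: the largest allowed
# square (512 px, shrinking to 256 px with a warning on small detectors)
# at maximal clearance from the targets, with >= margin_mm of margin.
place_nnps_region <- function(dim, spacing_mm, target_boxes,
                              margin_mm = 5, size = 512L) {
  margin_px <- ceiling(margin_mm / spacing_mm)
  try_size <- function(sz) {
    if (sz > min(dim)) return(NULL)
    rpos <- unique(c(seq(1L, dim[1] - sz + 1L, by = 16L), dim[1] - sz + 1L))
    cpos <- unique(c(seq(1L, dim[2] - sz + 1L, by = 16L), dim[2] - sz + 1L))
    best <- NULL; best_score <- -Inf
    for (r in rpos) for (cc in cpos) {
      cand <- roi_rect(r, r + sz - 1L, cc, cc + sz - 1L)
      score <- Inf
      for (b in target_boxes) {
        # Chebyshev gap between rectangles (negative if overlapping)
        dr <- max(b$row1 - cand$row2, cand$row1 - b$row2, 0)
        dc <- max(b$col1 - cand$col2, cand$col1 - b$col2, 0)
        gap <- if (roi_overlaps(cand, b)) -1 else max(dr, dc)
        score <- min(score, gap)
      }
      if (score > best_score) { best_score <- score; best <- cand }
    }
    if (best_score >= margin_px) best else NULL
  }
  reg <- try_size(512L)
  if (!is.null(reg) && size >= 512L) return(list(region = reg, warning = NULL))
  reg <- try_size(256L)
  if (!is.null(reg))
    return(list(region = reg,
                warning = "NNPS region shrunk to 256 x 256 px (detector too small for 512 x 512)"))
  list(region = NULL, warning = NULL)
}

# Assemble a full RoiSet from target geometry (used both for simulator
# ground truth and for the output of automatic localization).
build_roi_set <- function(dim, spacing_mm, cu_center_px, cu_side_px,
                          angle_deg, al_center_px, al_side_px,
                          sdnr_roi_mm = 5, bg_offset_mm = 10,
                          require_nnps = TRUE) {
  warnings <- character()
  cu_square <- list(center_px = cu_center_px, side_px = cu_side_px,
                    angle_deg = angle_deg)
  al_square <- list(center_px = al_center_px, side_px = al_side_px)
  al_roi <- roi_square_mm(al_center_px, sdnr_roi_mm, spacing_mm)
  cu_box <- cu_bounding_box(cu_square, inflate_px = 2)
  bg <- NULL
  offsets_mm <- if (require_nnps) bg_offset_mm else
    bg_offset_mm * c(1, 0.8, 0.6, 0.4, 0.2)
  for (off_mm in offsets_mm) {
    off_px <- (al_side_px / 2 + off_mm / spacing_mm)
    for (sgn in c(1, -1)) {
      cand_center <- al_center_px + c(0, sgn * off_px)
      cand <- roi_square_mm(cand_center, sdnr_roi_mm, spacing_mm)
      if (roi_inside(cand, dim) && !roi_overlaps(cand, cu_box) &&
          !roi_overlaps(cand, al_roi)) { bg <- cand; break }
    }
    if (!is.null(bg)) {
      if (off_mm != bg_offset_mm)
        warnings <- c(warnings, sprintf(
          "background ROI offset reduced to %.1f mm (image too small)", off_mm))
      break
    }
  }
  if (is.null(bg))
    stop("cannot place background ROI ", bg_offset_mm,
         " mm from the Al square inside the image")
  al_box <- roi_square_mm(al_center_px, al_side_px * spacing_mm, spacing_mm)
  nn <- place_nnps_region(dim, spacing_mm, list(cu_box, al_box))
  if (is.null(nn$region)) {
    if (require_nnps)
      stop("cannot place a homogeneous NNPS region clear of the targets")
    warnings <- c(warnings, "image too small for an NNPS region; none placed")
  }
  if (!is.null(nn$warning)) warnings <- c(warnings, nn$warning)
  rs <- new_roi_set(cu_square, al_square, al_roi, bg, nn$region,
                    cu_edge_segments(cu_square), warnings)
  validate_roi_set(rs, dim)
  rs
}

# Invariant checks shared by build and manual override.
validate_roi_set <- function(rs, dim) {
  cu_box <- cu_bounding_box(rs$cu_square)
  regions <- list(al_roi = rs$al_roi, background_roi = rs$background_roi)
  if (!is.null(rs$nnps_region)) regions$nnps_region <- rs$nnps_region
  for (nm in names(regions)) {
    if (!roi_inside(regions[[nm]], dim))
      stop("roi_set invalid: ", nm, " outside the image")
  }
  if (roi_npix(rs$al_roi) != roi_npix(rs$background_roi))
    stop("roi_set invalid: al_roi and background_roi differ in pixel count")
  pairs <- utils::combn(names(regions), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (roi_overlaps(regions[[a]], regions[[b]]))
      stop("roi_set invalid: ", a, " overlaps ", b)
  }
  for (nm in setdiff(names(regions), "al_roi")) {
    if (roi_overlaps(regions[[nm]], cu_box))
      stop("roi_set invalid: ", nm, " overlaps the Cu square")
  }
  invisible(rs)
}

#' Apply manual overrides to a located ROI set
#'
#' Replaces any of `cu_square`, `al_roi`, `background_roi`, `nnps_region`
#' (and, for `cu_square`, recomputes the edge segments) and revalidates the
#' merged set against the geometric invariants.
#'
#' @param roiset a `roi_set`
#' @param edits named list of replacement elements
#' @param dim image dimension `c(rows, cols)` for bounds checking
#' @return the merged, revalidated `roi_set`
#' @export
override_rois <- function(roiset, edits, dim) {
  stopifnot(inherits(roiset, "roi_set"))
  allowed <- c("cu_square", "al_square", "al_roi", "background_roi", "nnps_region")
  bad <- setdiff(names(edits), allowed)
  if (length(bad)) stop("unknown roi_set fields in edits: ", paste(bad, collapse = ", "))
  for (nm in names(edits)) roiset[[nm]] <- edits[[nm]]
  if ("cu_square" %in% names(edits))
    roiset$edge_segments <- cu_edge_segments(roiset$cu_square)
  validate_roi_set(roiset, dim)
  roiset
}
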