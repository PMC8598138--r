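# PhantomImage: the unit of analysis.

#' Construct a phantom image
#'
#' @param pixels numeric matrix of detector units (rows = image rows,
#'   origin top-left); higher value = more signal
#' @param pixel_spacing_mm pixel pitch `c(row_mm, col_mm)`, both > 0
#' @param modality `"radiography"` or `"mammography"`
#' @param presentation_state `"for_processing"`, `"for_presentation"` or
#'   `"unknown"`
#' @param metadata an [acquisition_metadata()]
#' @return object of class `phantom_image`
#' @export
new_phantom_image <- function(pixels, pixel_spacing_mm,
                              modality = c("radiography", "mammography"),
                              presentation_state = c("for_processing",
                                                     "for_presentation",
                                                     "unknown"),
                              metadata = acquisition_metadata()) {
  modality <- match.arg(modality)
  presentation_state <- match.arg(presentation_state)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty numeric matrix")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  storage.mode(pixels) <- "double"   # integer input would overflow cumsums
  pixel_spacing_mm <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
  if (any(pixel_spacing_mm <= 0)) stop("pixel_spacing_mm must be > 0")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 modality = modality, presentation_state = presentation_state,
                 metadata = metadata),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image %d x %d px, %.4g x %.4g mm/px, %s, %s>\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$modality, x$presentation_state))
  md <- x$metadata
  cat(sprintf("  kVp=%s mAs=%s EI=%s detector=%s\n",
              format(md$kvp), format(md$tube_load_mas),
              format(md$exposure_index), format(md$detector_id)))
  invisible(x)
}

#' @export
dim.phantom_image <- function(x) dim(x$pixels)

# Nyquist frequency (cycles/mm) along columns (axis 2 by default)
nyquist_freq <- function(image_or_spacing) {
  p <- if (inherits(image_or_spacing, "phantom_image"))
    image_or_spacing$pixel_spacing_mm[1] else image_or_spacing
  1 / (2 * p)
}
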