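#' Fluorescence field image with spatial calibration and region metadata
#'
#' A `field_image` wraps one single-channel micrograph field (or one plane of
#' a z-stack) as a numeric matrix in `[0, 1]` together with the spatial
#' calibration and the whole-mount metadata the downstream quantifications
#' stratify on: retinal layer, area (quadrant), zone (concentric ring),
#' animal and experimental group.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows x cols).
#' @param pixel_size_um Physical size of one pixel side, in micrometres.
#' @param magnification Objective magnification, `"20x"` or `"40x"`.
#' @param layer Retinal layer: `"OPL"`, `"IPL"`, `"NFL-GCL"` or
#'   `"GCL-nuclei"` (nuclear labelling in the ganglion cell layer).
#' @param area Retinal area (quadrant): `"superior"`, `"inferior"`,
#'   `"nasal"` or `"temporal"`.
#' @param zone Concentric zone: `"peripapillary"`, `"intermediate"` or
#'   `"peripheral"`.
#' @param animal_id Animal identifier (any scalar).
#' @param group Experimental group, `"WT"` or `"DS"`.
#' @param eye Eye laterality, `"left"` or `"right"`; governs the
#'   nasal/temporal mapping of the sampling geometry.
#'
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um = 1,
                        magnification = c("20x", "40x"),
                        layer = NA_character_, area = NA_character_,
                        zone = NA_character_, animal_id = NA_character_,
                        group = NA_character_, eye = "right") {
  magnification <- match.arg(magnification)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("field_image: pixels must be finite")
  if (any(pixels < 0))
    stop("field_image: pixels must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("field_image: pixel_size_um must be a positive scalar")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         magnification = magnification, layer = layer, area = area,
         zone = zone, animal_id = animal_id, group = group, eye = eye),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> %d x %d px, %.4g um/px (%s)\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$magnification))
  cat(sprintf("  layer=%s area=%s zone=%s animal=%s group=%s\n",
              x$layer, x$area, x$zone, x$animal_id, x$group))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$pixels)

# Accept either a field_image or a bare matrix; return the matrix.
as_pixels <- function(img) {
  if (inherits(img, "field_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a field_image or a numeric matrix")
}

# Rebuild a field_image around new pixels, keeping metadata.
with_pixels <- function(img, pixels) {
  if (inherits(img, "field_image")) {
    img$pixels <- pixels
    img
  } else pixels
}

#' Physical field area in mm^2
#'
#' @param img A `field_image`.
#' @return Field area in mm^2 computed from the pixel grid and calibration.
#' @export
field_image_area_mm2 <- function(img) {
  stopifnot(inherits(img, "field_image"))
  d <- dim(img$pixels)
  d[1] * d[2] * img$pixel_size_um^2 * 1e-6
}
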