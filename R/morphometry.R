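#' Binarize a field into a positive-staining mask
#'
#' Converts a grayscale field into a binary mask of positively stained
#' pixels, either with Otsu's method learned per field or with a fixed
#' threshold. The method and the threshold actually applied are recorded
#' on the mask for audit.
#'
#' @param img A `field_image` or numeric matrix in `[0, 1]`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Cut value when `method = "fixed"`; pixels strictly
#'   above the threshold are foreground.
#' @return A logical matrix with attributes `method` and `threshold`.
#' @export
binarize_field <- function(img, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  m <- as_pixels(img)
  if (method == "otsu") {
    if (diff(range(m)) == 0)
      stop("binarize_field: constant image, Otsu threshold is degenerate")
    threshold <- EBImage::otsu(EBImage::Image(m), range = range(m))
  }
  mask <- m > threshold
  attr(mask, "method") <- method
  attr(mask, "threshold") <- as.numeric(threshold)
  mask
}

# Connected component of `mask` containing seed_point; returns linear
# pixel indices. Errors if the seed lies on background.
component_at <- function(mask, seed_point, connectivity = 8) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  r <- as.integer(round(seed_point[1])); c <- as.integer(round(seed_point[2]))
  if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask))
    stop("seed point outside image bounds")
  if (!mask[r, c]) stop("seed point lies on background")
  labels <- segment_nonzero(mask * 1, connectivity)
  which(labels == labels[r, c])
}

#' Occupied area of the cell at a seed point
#'
#' The area of positive staining belonging to one cell: the pixel count of
#' the connected foreground component containing the seed, converted to
#' mm^2 through the pixel calibration.
#'
#' @param mask Binary mask from [binarize_field()].
#' @param seed_point `(row, col)` on a foreground pixel of the cell.
#' @param pixel_size_um Pixel side in micrometres.
#' @param connectivity 4 or 8 (default 8).
#' @return Occupied area in mm^2.
#' @export
occupied_cell_area <- function(mask, seed_point, pixel_size_um,
                               connectivity = 8) {
  px <- component_at(mask, seed_point, connectivity)
  length(px) * pixel_size_um^2 * 1e-6
}

# Number of lattice points (pixel centres) inside or on the convex hull of
# a set of pixels given as (row, col). Degenerate (collinear) sets fall
# back to the pixel count itself.
hull_pixel_count <- function(rc) {
  rc <- unique(rc)
  n <- nrow(rc)
  if (n <= 2) return(n)
  h <- grDevices::chull(rc[, 2], rc[, 1])   # x = col, y = row
  if (length(h) <= 2) return(n)             # collinear
  hx <- rc[h, 2]; hy <- rc[h, 1]
  rr <- seq(min(rc[, 1]), max(rc[, 1]))
  cc <- seq(min(rc[, 2]), max(rc[, 2]))
  g <- expand.grid(row = rr, col = cc)
  inside <- pracma::inpolygon(g$col, g$row, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Arbor area of the cell at a seed point
#'
#' The area of the polygon spanned by the most distal processes of a cell,
#' formalized as the convex hull of the cell's connected component. The
#' area is the number of pixel centres inside or on the hull (what an
#' image-analysis polygon ROI measures), converted to mm^2. It is always
#' at least the occupied area of the same cell.
#'
#' @inheritParams occupied_cell_area
#' @return Arbor area in mm^2.
#' @export
arbor_area <- function(mask, seed_point, pixel_size_um, connectivity = 8) {
  px <- component_at(mask, seed_point, connectivity)
  nr <- nrow(mask)
  rc <- cbind(((px - 1L) %% nr) + 1L, ((px - 1L) %/% nr) + 1L)
  hull_pixel_count(rc) * pixel_size_um^2 * 1e-6
}

#' Randomly select whole cells for per-cell morphometry
#'
#' Draws `n` cells without replacement from the detected cells whose
#' connected component does not touch the image border, so that the entire
#' soma and all processes lie within the field of analysis. The draw is
#' seeded and reproducible.
#'
#' @param mask Binary mask of the field.
#' @param detections Tibble with `row`, `col` of detected cell points
#'   (e.g. from [count_cells()]), each on or near a foreground component.
#' @param n Number of cells to select (protocol default 3).
#' @param seed RNG seed for the draw.
#' @param connectivity 4 or 8.
#' @return Tibble of `n` rows: `row`, `col` seed points of selected cells.
#' @export
sample_cells_for_morphometry <- function(mask, detections, n = 3, seed = 1,
                                         connectivity = 8) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(detections) == 0) stop("no detections supplied")
  labels <- segment_nonzero(mask * 1, connectivity)
  border_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
  border_labels <- border_labels[border_labels > 0L]
  # snap each detection to the nearest foreground pixel's component
  lab_of <- vapply(seq_len(nrow(detections)), function(i) {
    r <- as.integer(round(detections$row[i]))
    c <- as.integer(round(detections$col[i]))
    r <- min(max(r, 1L), nrow(labels)); c <- min(max(c, 1L), ncol(labels))
    if (labels[r, c] > 0L) return(labels[r, c])
    fg <- which(labels > 0L)
    if (length(fg) == 0) return(0L)
    fr <- ((fg - 1L) %% nrow(labels)) + 1L
    fc <- ((fg - 1L) %/% nrow(labels)) + 1L
    labels[fg[which.min((fr - r)^2 + (fc - c)^2)]]
  }, integer(1))
  eligible <- which(lab_of > 0L & !(lab_of %in% border_labels) &
                      !duplicated(lab_of))
  if (length(eligible) < n)
    stop(sprintf("only %d whole (non-border) cells available, %d requested",
                 length(eligible), n))
  sel <- withr::with_seed(seed, sample(eligible, n))
  # seed points: a foreground pixel of each selected component
  out <- lapply(sel, function(i) {
    px <- which(labels == lab_of[i])[1]
    tibble::tibble(row = ((px - 1L) %% nrow(labels)) + 1L,
                   col = ((px - 1L) %/% nrow(labels)) + 1L)
  })
  dplyr::bind_rows(out)
}

#' GFAP-labelled retinal area of a field
#'
#' The fraction of the field positive for astroglial staining: foreground
#' pixels after binarization over total pixels, with areas in mm^2 through
#' the calibration.
#'
#' @param img A `field_image` (astrocyte channel).
#' @param method,threshold Passed to [binarize_field()].
#' @return A list of class `coverage_result`: `fraction`,
#'   `labelled_area_mm2`, `field_area_mm2`, `method`, `threshold`.
#' @export
gfap_retinal_area <- function(img, method = c("otsu", "fixed"),
                              threshold = 0.5) {
  stopifnot(inherits(img, "field_image"))
  mask <- binarize_field(img, method, threshold)
  frac <- mean(mask)
  total <- field_image_area_mm2(img)
  structure(list(fraction = frac,
                 labelled_area_mm2 = frac * total,
                 field_area_mm2 = total,
                 method = attr(mask, "method"),
                 threshold = attr(mask, "threshold")),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> fraction %.4f (%.5g / %.5g mm^2), %s @ %.4g\n",
              x$fraction, x$labelled_area_mm2, x$field_area_mm2,
              x$method, x$threshold))
  invisible(x)
}
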