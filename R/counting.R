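#' Parameters of the automatic cell counter
#'
#' The counter suppresses pixels below a fraction of the per-image maximum,
#' segments the surviving pixels into connected components, takes one centre
#' of mass per component and merges centres closer than a minimum distance,
#' so that one cell split across adjacent segments is counted once.
#'
#' @param threshold Fraction of the image maximum below which pixels are
#'   zeroed; strictly-below pixels are suppressed. Default 0.2.
#' @param min_distance_px Merging radius in pixels: centroids strictly
#'   closer than this are considered the same cell. The study protocol
#'   leaves its value to the operator; a sensible default is 0.8 x the
#'   expected soma diameter in pixels.
#' @param connectivity Pixel adjacency for segmentation, 4 or 8. Default 8,
#'   so that thin diagonal processes do not fragment a cell.
#' @param centroid `"intensity"` (intensity-weighted centre of mass,
#'   default) or `"geometric"`.
#'
#' @return A `counting_params` list.
#' @export
counting_params <- function(threshold = 0.2, min_distance_px = 10,
                            connectivity = 8,
                            centroid = c("intensity", "geometric")) {
  centroid <- match.arg(centroid)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (!is.numeric(min_distance_px) || min_distance_px < 0)
    stop("min_distance_px must be >= 0")
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  structure(list(threshold = threshold, min_distance_px = min_distance_px,
                 connectivity = connectivity, centroid = centroid),
            class = "counting_params")
}

#' Average a z-stack into a single projection
#'
#' Pixelwise arithmetic mean over the planes of a stack. Metadata (and
#' calibration) of the first plane are retained. A max-intensity projection
#' is available as an extended-focus-style alternative.
#'
#' @param stack A single `field_image`/matrix or a list of them, all with
#'   identical dimensions.
#' @param method `"mean"` (default) or `"max"`.
#' @return A single image of the same type as the first plane.
#' @export
z_project <- function(stack, method = c("mean", "max")) {
  method <- match.arg(method)
  if (inherits(stack, "field_image") || is.matrix(stack)) stack <- list(stack)
  if (length(stack) == 0) stop("z_project: empty stack")
  mats <- lapply(stack, as_pixels)
  d <- dim(mats[[1]])
  for (m in mats)
    if (!identical(dim(m), d)) stop("z_project: plane shape mismatch")
  acc <- Reduce(if (method == "mean") `+` else pmax, mats)
  if (method == "mean") acc <- acc / length(mats)
  with_pixels(stack[[1]], acc)
}

#' Normalize an image to its maximum pixel value
#'
#' Divides by the image maximum so values span `[0, 1]`; the pixel order is
#' preserved. An all-zero image cannot be normalized.
#'
#' @param img A `field_image` or numeric matrix.
#' @return Image of the same type with maximum exactly 1.
#' @export
normalize_max <- function(img) {
  m <- as_pixels(img)
  mx <- max(m)
  if (mx <= 0) stop("normalize_max: degenerate all-zero image")
  with_pixels(img, m / mx)
}

#' Suppress pixels strictly below a threshold
#'
#' Pixels with value `< threshold` are set to 0; pixels at or above the
#' threshold keep their value (the inequality is strict on the low side).
#'
#' @param img Normalized image in `[0, 1]`.
#' @param threshold Fraction in (0, 1).
#' @return Image of the same type.
#' @export
threshold_suppress <- function(img, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold_suppress: threshold must be in (0, 1)")
  m <- as_pixels(img)
  m[m < threshold] <- 0
  with_pixels(img, m)
}

#' Label connected components of the non-zero pixels
#'
#' @param img Thresholded image (or binary mask); any non-zero pixel is
#'   foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer label matrix; 0 is background, components are labelled
#'   1..k in raster order of their first pixel.
#' @export
segment_nonzero <- function(img, connectivity = 8) {
  m <- as_pixels(img)
  fg <- m > 0
  if (!any(fg)) return(matrix(0L, nrow(m), ncol(m)))
  if (connectivity == 4) {
    lab <- EBImage::bwlabel(fg)   # bwlabel is 4-connected
    lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  } else if (connectivity == 8) {
    lab <- label_components_8(fg)
  } else stop("connectivity must be 4 or 8")
  relabel_raster_order(lab)
}

# 8-connected labeling: vectorized adjacency edge list + igraph components.
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  id <- seq_along(idx)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- id
  edges <- list()
  # neighbour offsets covering each unordered pair once: E, S, SE, SW
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- pos[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- rbind(id[ok][hit], nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  lab[idx] <- as.integer(comp)
  lab
}

# Make labels 1..k in raster order of first occurrence.
relabel_raster_order <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Centre of mass of each segment
#'
#' One centroid per labelled component, at subpixel precision. By default
#' centroids are intensity-weighted (centre of mass of the preserved
#' intensities); a geometric (unweighted) centroid is available.
#'
#' @param labels Integer label matrix from [segment_nonzero()].
#' @param img The image the labels were derived from (same shape).
#' @param weight `"intensity"` or `"geometric"`.
#' @return A tibble with columns `segment`, `row`, `col`, `n_pixels`.
#' @export
centers_of_mass <- function(labels, img, weight = c("intensity", "geometric")) {
  weight <- match.arg(weight)
  m <- as_pixels(img)
  stopifnot(identical(dim(labels), dim(m)))
  idx <- which(labels > 0L)
  if (length(idx) == 0)
    return(tibble::tibble(segment = integer(), row = numeric(),
                          col = numeric(), n_pixels = integer()))
  lab <- labels[idx]
  r <- ((idx - 1L) %% nrow(m)) + 1L
  c <- ((idx - 1L) %/% nrow(m)) + 1L
  w <- if (weight == "intensity") m[idx] else rep(1, length(idx))
  sw <- tapply(w, lab, sum)
  rw <- tapply(w * r, lab, sum) / sw
  cw <- tapply(w * c, lab, sum) / sw
  np <- tapply(rep(1L, length(idx)), lab, sum)
  seg <- as.integer(names(sw))
  ord <- order(seg)
  tibble::tibble(segment = seg[ord], row = as.numeric(rw)[ord],
                 col = as.numeric(cw)[ord], n_pixels = as.integer(np)[ord])
}

#' Merge points closer than a minimum distance into single detections
#'
#' Points strictly closer than `min_distance_px` belong to the same cell.
#' The relation is closed transitively (single linkage), so a chain of
#' nearby centroids collapses to one detection regardless of input order.
#' Each cluster is represented by the unweighted mean of its member points.
#'
#' @param points A tibble/data.frame with columns `row`, `col` and
#'   optionally `segment` and `n_pixels` (as from [centers_of_mass()]).
#' @param min_distance_px Merging radius; 0 merges nothing.
#' @return A tibble of detections: `row`, `col`, `n_points` (members),
#'   `n_pixels` (summed over members, if supplied), `segment_ids` (list
#'   column of contributing segment labels, if supplied).
#' @export
merge_min_distance <- function(points, min_distance_px) {
  if (min_distance_px < 0) stop("min_distance_px must be >= 0")
  points <- tibble::as_tibble(points)
  n <- nrow(points)
  if (n == 0)
    return(tibble::tibble(row = numeric(), col = numeric(),
                          n_points = integer(), n_pixels = integer(),
                          segment_ids = list()))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (min_distance_px > 0 && n > 1) {
    for (i in seq_len(n - 1)) {
      di <- sqrt((points$row[(i + 1):n] - points$row[i])^2 +
                 (points$col[(i + 1):n] - points$col[i])^2)
      for (j in which(di < min_distance_px)) {
        a <- find(i); b <- find(i + j)
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- match(root, unique(root))
  has_px <- "n_pixels" %in% names(points)
  has_seg <- "segment" %in% names(points)
  out <- lapply(seq_along(unique(root)), function(k) {
    mem <- which(grp == k)
    tibble::tibble(
      row = mean(points$row[mem]),
      col = mean(points$col[mem]),
      n_points = length(mem),
      n_pixels = if (has_px) sum(points$n_pixels[mem]) else NA_integer_,
      segment_ids = list(if (has_seg) points$segment[mem] else integer())
    )
  })
  dplyr::bind_rows(out)
}

#' Count cells in a field or z-stack
#'
#' The full automatic counting protocol: average the stack into a
#' z-projection, normalize to the image maximum, zero all pixels strictly
#' below the threshold fraction, segment the surviving pixels into
#' connected components, take one centre of mass per component, and merge
#' centroids closer than the minimum distance so each cell is counted once.
#' The normalization step makes the count invariant to uniform intensity
#' rescaling of the input.
#'
#' @param stack A `field_image`, matrix, or list of same-shape planes.
#' @param params A [counting_params()] object.
#' @param projection Passed to [z_project()] (`"mean"` or `"max"`).
#' @return A list with `count` (integer) and `detections` (tibble from
#'   [merge_min_distance()]).
#' @export
count_cells <- function(stack, params = counting_params(),
                        projection = "mean") {
  proj <- z_project(stack, method = projection)
  m <- as_pixels(proj)
  if (max(m) <= 0)
    return(list(count = 0L,
                detections = merge_min_distance(
                  tibble::tibble(row = numeric(), col = numeric()), 0)))
  norm <- normalize_max(proj)
  thr <- threshold_suppress(norm, params$threshold)
  labels <- segment_nonzero(thr, params$connectivity)
  cm <- centers_of_mass(labels, thr, weight = params$centroid)
  det <- merge_min_distance(cm, params$min_distance_px)
  list(count = nrow(det), detections = det)
}
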