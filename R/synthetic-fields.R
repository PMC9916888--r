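#' Specification of a synthetic fluorescence field
#'
#' Parameters of one simulated micrograph field: geometry of the cells to
#' place, a hard-core minimum spacing between cell centres, and the
#' background/noise model. Defaults describe a 512 x 512 px field covering
#' 0.1502 mm^2 (the 20x field of the whole-mount protocol), with cell
#' geometry plausible for retinal microglial plexuses.
#'
#' The background model must keep essentially all background pixels below
#' the downstream detection threshold (0.2 of the image maximum); the
#' constructor enforces `background_level + 2.33 * noise_sd < 0.2` so that
#' at least 99% of background pixels fall below it.
#'
#' @param image_shape Integer `(rows, cols)`.
#' @param pixel_size_um Micrometres per pixel (default 0.757, i.e. a
#'   512 px field side of sqrt(0.1502) mm).
#' @param n_cells Number of cells to place (>= 0).
#' @param min_spacing_px Hard-core minimum centre-to-centre distance; must
#'   exceed twice the soma radius when more than one cell is placed.
#' @param soma_radius_px Mean soma radius in px.
#' @param n_processes Mean number of primary processes per cell.
#' @param process_length_px Mean primary process length in px.
#' @param process_thickness_px Mean process thickness in px.
#' @param background_level Background intensity in `[0, 1)`.
#' @param noise_sd SD of additive Gaussian noise (clipped to `[0, 1]`).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return A `field_spec` list.
#' @export
field_spec <- function(image_shape = c(512, 512), pixel_size_um = 0.757,
                       n_cells = 20, min_spacing_px = 60,
                       soma_radius_px = 4, n_processes = 4,
                       process_length_px = 40, process_thickness_px = 2,
                       background_level = 0.05, noise_sd = 0.02,
                       seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            pixel_size_um > 0, n_cells >= 0, soma_radius_px > 0,
            process_length_px > 0, process_thickness_px > 0,
            n_processes >= 0, noise_sd >= 0,
            background_level >= 0, background_level < 1)
  if (n_cells > 1 && min_spacing_px <= 2 * soma_radius_px)
    stop("min_spacing_px must exceed 2 * soma_radius_px")
  if (background_level + 2.33 * noise_sd >= 0.2)
    stop("background_level + noise too high for downstream detection ",
         "threshold (need background_level + 2.33 * noise_sd < 0.2)")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 min_spacing_px = min_spacing_px,
                 soma_radius_px = soma_radius_px, n_processes = n_processes,
                 process_length_px = process_length_px,
                 process_thickness_px = process_thickness_px,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "field_spec")
}

# Hard-core placement by rejection sampling. Returns an n x 2 matrix of
# (row, col) centres with all pairwise distances >= min_spacing.
place_hardcore_centers <- function(n, shape, min_spacing, margin = 0,
                                   max_retries = 10000) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  lo <- c(1 + margin, 1 + margin)
  hi <- c(shape[1] - margin, shape[2] - margin)
  if (any(hi <= lo)) stop("margin leaves no room to place cells")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    if (tries >= max_retries)
      stop(sprintf(
        "infeasible density: placed %d of %d cells after %d retries",
        placed, n, max_retries))
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    ok <- placed == 0L ||
      min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
               (centers[seq_len(placed), 2] - cand[2])^2)) >= min_spacing
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    tries <- tries + 1L
  }
  centers
}

# Linear indices of pixels within `radius` of a centre, clipped to dim.
disk_pixels <- function(center, radius, dm) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dm[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dm[2], ceiling(center[2] + radius))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  hit <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  (g$col[hit] - 1L) * dm[1] + g$row[hit]
}

# Linear indices of pixels within `half` of the segment p0 -> p1.
segment_pixels <- function(p0, p1, half, dm) {
  pad <- ceiling(half) + 1L
  r0 <- max(1L, floor(min(p0[1], p1[1]) - pad))
  r1 <- min(dm[1], ceiling(max(p0[1], p1[1]) + pad))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - pad))
  c1 <- min(dm[2], ceiling(max(p0[2], p1[2]) + pad))
  if (r1 < r0 || c1 < c0) return(integer(0))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (g$row - p0[1])^2 + (g$col - p0[2])^2
  } else {
    t <- pmin(pmax(((g$row - p0[1]) * v[1] + (g$col - p0[2]) * v[2]) / len2,
                   0), 1)
    d2 <- (g$row - (p0[1] + t * v[1]))^2 + (g$col - (p0[2] + t * v[2]))^2
  }
  hit <- d2 <= half^2
  (g$col[hit] - 1L) * dm[1] + g$row[hit]
}

# Ground-truth bundle shared by all generators.
ground_truth <- function(cell_centers, cell_pixels, dm) {
  n <- nrow(cell_centers)
  arbor <- vapply(cell_pixels, function(px) {
    if (length(px) == 0) return(0)
    rc <- cbind(((px - 1L) %% dm[1]) + 1L, ((px - 1L) %/% dm[1]) + 1L)
    hull_pixel_count(rc)
  }, numeric(1))
  union_px <- unique(unlist(cell_pixels, use.names = FALSE))
  structure(list(cell_centers = cell_centers,
                 cell_pixels = cell_pixels,
                 true_arbor_area_px = arbor,
                 true_coverage_fraction = length(union_px) / prod(dm),
                 image_shape = dm),
            class = "ground_truth")
}

# Compose signal pixels into a noisy clipped image.
render_field <- function(signal, spec) {
  withCallingHandlers({
    img <- spec$background_level + signal * (1 - spec$background_level)
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
    matrix(img, spec$image_shape[1], spec$image_shape[2])
  }, warning = function(w) invokeRestart("muffleWarning"))
}

#' Simulate a ramified microglia-like field
#'
#' Places hard-core-spaced cells, each a filled soma disk from which
#' primary processes emerge as random-direction polylines with one or two
#' branch points, as in ramified retinal microglia. Ground truth records
#' every cell's centre, pixel mask and convex-hull arbor area.
#'
#' @param spec A [field_spec()].
#' @param meta Optional named list of `field_image` metadata (layer, area,
#'   zone, animal_id, group).
#' @return A list with `image` (a `field_image`) and `truth`
#'   (a `ground_truth`).
#' @export
simulate_microglia_field <- function(spec, meta = list()) {
  stopifnot(inherits(spec, "field_spec"))
  dm <- spec$image_shape
  withr::local_seed(spec$seed)
  margin <- min(spec$soma_radius_px + 1.3 * spec$process_length_px + 2,
                floor(min(dm) / 3))
  centers <- place_hardcore_centers(spec$n_cells, dm, spec$min_spacing_px,
                                    margin = margin)
  signal <- numeric(prod(dm))
  cell_pixels <- vector("list", spec$n_cells)
  half <- spec$process_thickness_px / 2
  for (i in seq_len(spec$n_cells)) {
    ctr <- centers[i, ]
    soma_r <- max(1.5, stats::rnorm(1, spec$soma_radius_px,
                                    0.15 * spec$soma_radius_px))
    soma <- disk_pixels(ctr, soma_r, dm)
    proc_px <- integer(0)
    k <- max(1L, stats::rpois(1, spec$n_processes))
    base_ang <- stats::runif(1, 0, 2 * pi)
    for (p in seq_len(k)) {
      ang <- base_ang + 2 * pi * (p - 1) / k + stats::rnorm(1, 0, 0.25)
      len <- spec$process_length_px * exp(stats::rnorm(1, 0, 0.2))
      # primary process: two segments with a kink at ~60% of the length
      kink <- ctr + (soma_r + 0.6 * len) * c(sin(ang), cos(ang))
      ang2 <- ang + stats::rnorm(1, 0, 0.45)
      tip <- kink + 0.4 * len * c(sin(ang2), cos(ang2))
      proc_px <- c(proc_px,
                   segment_pixels(ctr, kink, half, dm),
                   segment_pixels(kink, tip, half, dm))
      if (stats::runif(1) < 0.6) {  # secondary branch at the kink
        ang3 <- ang - stats::rnorm(1, 0.7, 0.2)
        btip <- kink + 0.35 * len * c(sin(ang3), cos(ang3))
        proc_px <- c(proc_px, segment_pixels(kink, btip, half * 0.8, dm))
      }
    }
    px <- unique(c(soma, proc_px))
    cell_pixels[[i]] <- px
    signal[soma] <- pmax(signal[soma], 0.9)
    pp <- setdiff(proc_px, soma)
    signal[pp] <- pmax(signal[pp], 0.65)
  }
  img <- render_field(signal, spec)
  fi <- do.call(field_image,
                c(list(pixels = img, pixel_size_um = spec$pixel_size_um),
                  meta))
  list(image = fi, truth = ground_truth(centers, cell_pixels, dm))
}

#' Simulate a honeycomb astrocyte plexus field
#'
#' Builds a jittered hexagonal network of astrocyte somata joined by
#' processes, then thickens the network either to a requested labelled
#' coverage fraction (matched by construction through the distance
#' transform of the network skeleton) or to the process thickness given in
#' the spec. Ground truth records the exact achieved coverage.
#'
#' @param spec A [field_spec()]; `n_cells` sets the lattice density.
#' @param target_coverage Optional fraction in `[0, 0.9]`; when `NULL`
#'   the coverage follows from `process_thickness_px`.
#' @param meta Optional `field_image` metadata.
#' @return A list with `image`, `truth` and `mask` (the labelled mask).
#' @export
simulate_astrocyte_field <- function(spec, target_coverage = NULL,
                                     meta = list()) {
  stopifnot(inherits(spec, "field_spec"))
  if (!is.null(target_coverage) &&
      (target_coverage < 0 || target_coverage > 0.9))
    stop("target_coverage must be in [0, 0.9]")
  dm <- spec$image_shape
  withr::local_seed(spec$seed)
  if (!is.null(target_coverage) && target_coverage == 0) {
    signal <- numeric(prod(dm))
    img <- render_field(signal, spec)
    fi <- do.call(field_image,
                  c(list(pixels = img, pixel_size_um = spec$pixel_size_um),
                    meta))
    tr <- ground_truth(matrix(numeric(0), 0, 2), list(), dm)
    return(list(image = fi, truth = tr,
                mask = matrix(FALSE, dm[1], dm[2])))
  }
  # jittered hexagonal lattice of somata at the density implied by n_cells
  n <- max(spec$n_cells, 4L)
  s <- sqrt(2 * prod(dm) / (sqrt(3) * n))
  rows <- seq(s / 2, dm[1] - s / 4, by = s * sqrt(3) / 2)
  centers <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    cols <- seq(s / 2 + off, dm[2] - s / 4, by = s)
    cbind(rows[i] + stats::rnorm(length(cols), 0, 0.12 * s),
          cols + stats::rnorm(length(cols), 0, 0.12 * s))
  }))
  centers[, 1] <- pmin(pmax(centers[, 1], 2), dm[1] - 1)
  centers[, 2] <- pmin(pmax(centers[, 2], 2), dm[2] - 1)
  # 1-px skeleton: somata plus processes joining lattice neighbours
  skel <- matrix(FALSE, dm[1], dm[2])
  d2 <- as.matrix(stats::dist(centers))
  for (i in seq_len(nrow(centers))) {
    skel[disk_pixels(centers[i, ], max(spec$soma_radius_px / 2, 1), dm)] <- TRUE
    nb <- which(d2[i, ] < 1.4 * s & seq_len(nrow(centers)) > i)
    for (j in nb)
      skel[segment_pixels(centers[i, ], centers[j, ], 0.5, dm)] <- TRUE
  }
  # distance of every pixel to the skeleton
  dist_to <- EBImage::distmap(EBImage::Image(1 - skel))
  dist_to <- matrix(as.numeric(dist_to), dm[1], dm[2])
  # sub-pixel dither breaks the heavy ties of the integer-lattice distance
  # values, so thickness acts continuously and quantiles land on target
  dd <- dist_to + stats::runif(length(dist_to), 0, 0.25)
  if (is.null(target_coverage)) {
    mask <- matrix(dd <= spec$process_thickness_px / 2, dm[1], dm[2])
  } else {
    q <- stats::quantile(dd, probs = target_coverage, type = 1)
    mask <- matrix(dd <= q, dm[1], dm[2])
  }
  achieved <- mean(mask)
  if (!is.null(target_coverage) && abs(achieved - target_coverage) > 0.02)
    stop(sprintf("unreachable coverage: target %.3f, achieved %.3f",
                 target_coverage, achieved))
  signal <- numeric(prod(dm))
  signal[mask] <- 0.8
  img <- render_field(signal, spec)
  fi <- do.call(field_image,
                c(list(pixels = img, pixel_size_um = spec$pixel_size_um),
                  meta))
  tr <- ground_truth(centers, rep(list(integer(0)), nrow(centers)), dm)
  tr$true_coverage_fraction <- achieved   # coverage is the measurand here
  list(image = fi, truth = tr, mask = mask)
}

#' Simulate a field of nucleus-like blobs
#'
#' Places `n_cells` Gaussian-profile blobs at hard-core-spaced centres
#' (emulating nuclear or somatic labelling of retinal ganglion cells and
#' amacrine cells). Blob peaks reach intensity 1 by construction.
#'
#' @param spec A [field_spec()]; `soma_radius_px` sets the blob scale
#'   (Gaussian sigma = soma_radius / 1.5).
#' @param centers Optional explicit n x 2 matrix of (row, col) centres,
#'   overriding random placement.
#' @param meta Optional `field_image` metadata.
#' @return A list with `image` and `truth`.
#' @export
simulate_nuclei_field <- function(spec, centers = NULL, meta = list()) {
  stopifnot(inherits(spec, "field_spec"))
  dm <- spec$image_shape
  withr::local_seed(spec$seed)
  sigma <- spec$soma_radius_px / 1.5
  if (is.null(centers)) {
    margin <- min(ceiling(3 * sigma) + 2, floor(min(dm) / 4))
    centers <- place_hardcore_centers(spec$n_cells, dm, spec$min_spacing_px,
                                      margin = margin)
  } else {
    centers <- as.matrix(centers)
    stopifnot(ncol(centers) == 2)
  }
  signal <- numeric(prod(dm))
  cell_pixels <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    ext <- ceiling(3 * sigma)
    r0 <- max(1L, floor(ctr[1]) - ext); r1 <- min(dm[1], ceiling(ctr[1]) + ext)
    c0 <- max(1L, floor(ctr[2]) - ext); c1 <- min(dm[2], ceiling(ctr[2]) + ext)
    g <- expand.grid(row = r0:r1, col = c0:c1)
    d2 <- (g$row - ctr[1])^2 + (g$col - ctr[2])^2
    v <- exp(-d2 / (2 * sigma^2))
    idx <- (g$col - 1L) * dm[1] + g$row
    signal[idx] <- pmax(signal[idx], v)
    cell_pixels[[i]] <- idx[d2 <= (2 * sigma)^2]
  }
  img <- render_field(signal, spec)
  fi <- do.call(field_image,
                c(list(pixels = img, pixel_size_um = spec$pixel_size_um),
                  meta))
  list(image = fi, truth = ground_truth(centers, cell_pixels, dm))
}
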