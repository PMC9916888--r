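#' Read a grayscale TIFF field (single plane or z-stack)
#'
#' Reads an 8- or 16-bit grayscale TIFF; intensities are returned scaled
#' to `[0, 1]` (the `tiff` package performs the bit-depth scaling).
#' Multi-page files come back as a list of planes. RGB or multi-channel
#' files are rejected explicitly.
#'
#' @param path Path to the TIFF file.
#' @param ... `field_image` metadata (pixel_size_um, magnification,
#'   layer, area, zone, animal_id, group), normally taken from a manifest.
#' @return A `field_image`, or a list of them for a multi-page file.
#' @export
read_field_tiff <- function(path, ...) {
  pages <- tiff::readTIFF(path, all = TRUE)
  mk <- function(m) {
    if (length(dim(m)) == 3) {
      if (dim(m)[3] == 1) m <- m[, , 1]
      else stop("read_field_tiff: RGB/multi-channel TIFF is unsupported; ",
                "supply single-channel grayscale")
    }
    field_image(pixels = m, ...)
  }
  out <- lapply(pages, mk)
  if (length(out) == 1) out[[1]] else out
}

#' Write a field image as a grayscale TIFF
#'
#' @param img A `field_image` or matrix in `[0, 1]`, or a list of planes.
#' @param path Output path.
#' @param bits 8 or 16 bits per sample (default 16).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(img, path, bits = 16) {
  planes <- if (inherits(img, "field_image") || is.matrix(img)) list(img)
            else img
  mats <- lapply(planes, as_pixels)
  tiff::writeTIFF(if (length(mats) == 1) mats[[1]] else mats,
                  path, bits.per.sample = bits)
  invisible(path)
}

#' Write a cohort simulation to disk
#'
#' Writes each field as a 16-bit grayscale TIFF with a JSON ground-truth
#' sidecar (cell centres, per-cell arbor areas, coverage fraction), and a
#' manifest CSV indexing every field's metadata — the single source of
#' metadata for later analysis runs.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- sim$index
  idx$path <- file.path(dir, paste0(idx$field_id, ".tif"))
  for (i in seq_len(nrow(idx))) {
    fld <- sim$fields[[idx$field_id[i]]]
    write_field_tiff(fld$image, idx$path[i])
    tr <- fld$truth
    jsonlite::write_json(
      list(cell_centers = unname(as.matrix(tr$cell_centers)),
           true_arbor_area_px = tr$true_arbor_area_px,
           true_coverage_fraction = tr$true_coverage_fraction),
      sub("\\.tif$", ".json", idx$path[i]), digits = NA, auto_unbox = TRUE)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(idx[, c("field_id", "animal_id", "group", "layer",
                           "area", "zone", "seed", "path")],
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Run the full quantification pipeline on a simulated cohort
#'
#' Glues the stages end to end: simulate the cohort, measure every field
#' (counting, morphometry, coverage), aggregate per stratification, and
#' run the group-comparison statistics for each metric. All tabular
#' outputs are written as CSV, the statistical summary as JSON, and a run
#' log records the seed and parameters for audit. The run is reproducible
#' given the seed.
#'
#' @param cohort A [cohort_spec()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param params A [counting_params()] for the counting stage.
#' @return A list: `measurements`, `summaries` (per metric x
#'   stratification), `stats` (per metric `group_comparison`s), `index`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         params = counting_params(min_distance_px = 12)) {
  t0 <- Sys.time()
  sim <- simulate_cohort(cohort)
  meas <- measure_cohort(sim, params = params)
  metrics <- unique(meas$metric)
  summaries <- list()
  stats_out <- list()
  for (m in metrics) {
    mm <- meas[meas$metric == m, ]
    summaries[[m]] <- list(
      total = aggregate_measurements(mm, "total"),
      by_area = aggregate_measurements(mm, "by_area"),
      by_zone = aggregate_measurements(mm, "by_zone"))
    stats_out[[m]] <- list(
      by_area = tryCatch(compare_groups(mm, "by_area"),
                         error = function(e) NULL),
      by_zone = tryCatch(compare_groups(mm, "by_zone"),
                         error = function(e) NULL))
  }
  res <- list(measurements = meas, summaries = summaries,
              stats = stats_out, index = sim$index)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    for (m in metrics)
      for (s in names(summaries[[m]]))
        utils::write.csv(summaries[[m]][[s]],
                         file.path(out_dir, sprintf("summary_%s_%s.csv",
                                                    m, s)),
                         row.names = FALSE)
    stats_json <- lapply(stats_out, function(per_metric)
      lapply(per_metric, function(gc) {
        if (is.null(gc)) return(NULL)
        list(anova = if (inherits(gc$anova, "anova_result"))
               as.list(gc$anova$table) else gc$anova,
             posthoc = if (!is.null(gc$posthoc))
               as.list(gc$posthoc[, c("stratum", "diff", "p_adj",
                                      "stars")]),
             levene_p = if (inherits(gc$anova, "anova_result"))
               gc$anova$levene_p)
      }))
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         digits = NA, auto_unbox = TRUE)
    log <- c(sprintf("seed: %d", cohort$seed),
             sprintf("n_per_group: %d", cohort$n_per_group),
             sprintf("layers: %s", paste(cohort$plan$layers,
                                         collapse = ",")),
             sprintf("counting: threshold=%g min_distance=%g conn=%d",
                     params$threshold, params$min_distance_px,
                     params$connectivity),
             sprintf("fields: %d", nrow(sim$index)),
             sprintf("elapsed_s: %.1f",
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  res
}
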