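#' Specification of a synthetic two-group cohort
#'
#' Describes a WT vs DS cohort: animals per group (default 6 and 6, the
#' design of the whole-mount study), the per-retina sampling plan (one
#' field per (area, zone) sector per layer), the base field parameters,
#' and multiplicative WT-to-DS effect sizes on generator parameters.
#'
#' `effect_sizes` is a named list of positive factors applied to the DS
#' group's field specs: recognised names are `process_length`,
#' `soma_radius`, `process_thickness`, `n_cells` and `coverage`. A nested
#' list keyed by layer (e.g. `list(OPL = list(process_length = 0.7))`)
#' restricts a factor to fields of that layer; flat entries apply to all
#' layers.
#'
#' @param n_per_group Animals per group (the study design uses 6 and 6;
#'   single-animal cohorts are allowed for design arithmetic, but group
#'   statistics need at least 2).
#' @param plan A [sampling_plan()]; its layers decide which field types
#'   are generated (`"OPL"`, `"IPL"`, `"NFL-GCL"` are microglia plexuses,
#'   `"GFAP"` an astrocyte field, `"GCL-nuclei"` a nuclei field).
#' @param base_spec A [field_spec()] used for every WT field.
#' @param effect_sizes Named list of multiplicative DS effects (see
#'   Details). Empty list = null cohort.
#' @param gfap_target_coverage Mean labelled-area fraction of WT
#'   astrocyte fields (DS fields get it scaled by the `coverage` factor).
#' @param gfap_coverage_cv Field-to-field lognormal variability of the
#'   coverage target (default 0.10), emulating biological and staining
#'   variation between fields; 0 makes every field hit the mean exactly.
#' @param seed Cohort seed; per-field seeds derive deterministically.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 6,
                        plan = sampling_plan(layers = c("OPL", "IPL",
                                                        "NFL-GCL")),
                        base_spec = field_spec(),
                        effect_sizes = list(),
                        gfap_target_coverage = 0.3,
                        gfap_coverage_cv = 0.10,
                        seed = 1) {
  stopifnot(n_per_group >= 1, inherits(plan, "sampling_plan"),
            inherits(base_spec, "field_spec"))
  flat <- unlist(effect_sizes)
  if (length(flat) && any(flat <= 0)) stop("effect factors must be > 0")
  structure(list(n_per_group = as.integer(n_per_group), plan = plan,
                 base_spec = base_spec, effect_sizes = effect_sizes,
                 gfap_target_coverage = gfap_target_coverage,
                 gfap_coverage_cv = gfap_coverage_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Effect factors in force for one layer: flat entries + layer overrides.
effects_for_layer <- function(effect_sizes, layer) {
  flat <- effect_sizes[!vapply(effect_sizes, is.list, logical(1))]
  nested <- effect_sizes[vapply(effect_sizes, is.list, logical(1))]
  eff <- list(process_length = 1, soma_radius = 1, process_thickness = 1,
              n_cells = 1, coverage = 1)
  for (nm in names(flat)) eff[[nm]] <- flat[[nm]]
  if (layer %in% names(nested))
    for (nm in names(nested[[layer]])) eff[[nm]] <- nested[[layer]][[nm]]
  eff
}

# Apply DS effect factors to a field spec.
scale_spec <- function(spec, eff) {
  spec$process_length_px <- spec$process_length_px * eff$process_length
  spec$soma_radius_px <- spec$soma_radius_px * eff$soma_radius
  spec$process_thickness_px <- spec$process_thickness_px * eff$process_thickness
  spec$n_cells <- max(0L, as.integer(round(spec$n_cells * eff$n_cells)))
  spec
}

# Deterministic per-field seed below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Simulate a full image cohort
#'
#' Generates one field image (with ground truth) per animal x layer x
#' (area, zone) sector, with DS animals' field specs scaled by the cohort
#' effect sizes. Per-field seeds derive deterministically from the cohort
#' seed and the field index, so the cohort is reproducible field by field.
#'
#' @param cohort A [cohort_spec()].
#' @return A list with `index` (tibble: field_id, group, animal_id,
#'   layer, area, zone, seed) and `fields` (named list of generator
#'   outputs, each with `image` and `truth`).
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  inv <- plan_fields(cohort$plan, cohort$n_per_group)$inventory
  inv$animal_id <- paste0(inv$group, inv$retina)
  inv$field_id <- sprintf("F%04d", seq_len(nrow(inv)))
  inv$seed <- derive_seed(cohort$seed, seq_len(nrow(inv)))
  fields <- vector("list", nrow(inv))
  names(fields) <- inv$field_id
  for (i in seq_len(nrow(inv))) {
    layer <- inv$layer[i]
    spec <- cohort$base_spec
    eff <- effects_for_layer(cohort$effect_sizes, layer)
    is_ds <- inv$group[i] == "DS"
    if (is_ds) spec <- scale_spec(spec, eff)
    spec$seed <- inv$seed[i]
    meta <- list(layer = layer, area = inv$area[i], zone = inv$zone[i],
                 animal_id = inv$animal_id[i], group = inv$group[i])
    fields[[i]] <- switch(
      layer,
      "GFAP" = {
        tc <- cohort$gfap_target_coverage * (if (is_ds) eff$coverage else 1)
        if (cohort$gfap_coverage_cv > 0)
          tc <- tc * withr::with_seed(
            derive_seed(inv$seed[i], 1),
            exp(stats::rnorm(1, 0, cohort$gfap_coverage_cv)))
        simulate_astrocyte_field(spec, target_coverage = min(tc, 0.9),
                                 meta = meta)
      },
      "GCL-nuclei" = simulate_nuclei_field(spec, meta = meta),
      simulate_microglia_field(spec, meta = meta))
  }
  list(index = tibble::as_tibble(inv), fields = fields)
}

#' Measure every field of a simulated cohort
#'
#' Runs the quantification appropriate to each field's layer: automatic
#' cell counting for microglia and nuclei fields, per-cell morphometry of
#' randomly sampled whole cells for microglia fields, and labelled-area
#' fraction for astrocyte fields. Returns tidy field measurements ready
#' for [aggregate_measurements()] and the statistics battery.
#'
#' @param sim Output of [simulate_cohort()].
#' @param params A [counting_params()] for the counting stages.
#' @param n_cells_sampled Whole cells measured per microglia field
#'   (protocol default 3).
#' @param binarize_method Binarization for morphometry and coverage.
#' @return Tibble with columns `field_id`, `animal_id`, `group`, `layer`,
#'   `area`, `zone`, `metric`, `value`.
#' @export
measure_cohort <- function(sim, params = counting_params(min_distance_px = 12),
                           n_cells_sampled = 3,
                           binarize_method = "otsu") {
  rows <- list()
  for (i in seq_len(nrow(sim$index))) {
    info <- sim$index[i, ]
    fld <- sim$fields[[info$field_id]]
    img <- fld$image
    base <- tibble::tibble(field_id = info$field_id,
                           animal_id = info$animal_id, group = info$group,
                           layer = info$layer, area = info$area,
                           zone = info$zone)
    if (info$layer == "GFAP") {
      cov <- gfap_retinal_area(img, method = binarize_method)
      rows[[length(rows) + 1]] <-
        dplyr::mutate(base, metric = "gfap_fraction", value = cov$fraction)
    } else {
      cc <- count_cells(img, params)
      rows[[length(rows) + 1]] <-
        dplyr::mutate(base, metric = "cell_count", value = cc$count)
      if (info$layer %in% c("OPL", "IPL", "NFL-GCL") && cc$count > 0) {
        mask <- binarize_field(img, method = binarize_method)
        seeds <- tryCatch(
          sample_cells_for_morphometry(mask, cc$detections,
                                       n = n_cells_sampled,
                                       seed = info$seed),
          error = function(e) NULL)
        if (!is.null(seeds)) {
          occ <- vapply(seq_len(nrow(seeds)), function(k)
            occupied_cell_area(mask, c(seeds$row[k], seeds$col[k]),
                               img$pixel_size_um), numeric(1))
          arb <- vapply(seq_len(nrow(seeds)), function(k)
            arbor_area(mask, c(seeds$row[k], seeds$col[k]),
                       img$pixel_size_um), numeric(1))
          rows[[length(rows) + 1]] <-
            dplyr::mutate(base, metric = "occupied_area_mm2",
                          value = mean(occ))
          rows[[length(rows) + 1]] <-
            dplyr::mutate(base, metric = "arbor_area_mm2", value = mean(arb))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Expected multiplicative effect of parameter factors on each metric:
# arbor area scales with the square of process length; occupied area with
# process thickness x length; counts with cell number; coverage directly.
metric_effect <- function(eff, metric) {
  switch(metric,
         arbor_area_mm2 = eff$process_length^2,
         occupied_area_mm2 = eff$process_thickness * eff$process_length *
           eff$soma_radius,
         cell_count = eff$n_cells,
         gfap_fraction = eff$coverage,
         1)
}

# Plausible per-field baselines for each metric at the 20x calibration.
metric_baseline <- function(metric) {
  switch(metric,
         cell_count = 50,
         arbor_area_mm2 = 3.5e-3,
         occupied_area_mm2 = 5e-4,
         gfap_fraction = 0.30,
         stop("unknown metric: ", metric))
}

#' Draw measurement-level cohort data from the generator's model
#'
#' Samples per-field metric values directly from the hierarchical
#' distributional model that the image generator realizes: a lognormal
#' animal effect (between-retina variability) times lognormal field noise
#' around the metric baseline, with the DS group's mean scaled by the
#' effect implied by the cohort's parameter factors. This is the fast path
#' used for statistical calibration at hundreds of replicate cohorts,
#' where rendering every image would add nothing to the quantity under
#' test.
#'
#' @param cohort A [cohort_spec()].
#' @param metric One of `"cell_count"`, `"arbor_area_mm2"`,
#'   `"occupied_area_mm2"`, `"gfap_fraction"`.
#' @param layer Layer label attached to the rows (and used to look up
#'   layer-specific effect factors).
#' @param animal_cv Coefficient of variation of a shared animal effect.
#'   Default 0, matching the image generator, in which every field is an
#'   independent draw given its group's field parameters. Positive values
#'   emulate between-retina heterogeneity; note that the fixed-effects
#'   ANOVA downstream assumes independent animal x stratum values and is
#'   anticonservative when strata share an animal effect.
#' @param field_cv Coefficient of variation of per-field noise.
#' @param seed RNG seed (defaults to the cohort seed).
#' @return Tidy tibble of field measurements (one row per animal x
#'   sector): `animal_id`, `group`, `layer`, `area`, `zone`, `metric`,
#'   `value`. Counts are Poisson draws, hence integers.
#' @export
simulate_measurements <- function(cohort, metric = "arbor_area_mm2",
                                  layer = "OPL", animal_cv = 0,
                                  field_cv = 0.18, seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_spec"))
  withr::local_seed(seed)
  eff <- effects_for_layer(cohort$effect_sizes, layer)
  mu <- metric_baseline(metric)
  out <- list()
  for (grp in c("WT", "DS")) {
    gmu <- mu * (if (grp == "DS") metric_effect(eff, metric) else 1)
    for (a in seq_len(cohort$n_per_group)) {
      amu <- gmu * exp(stats::rnorm(1, 0, animal_cv))
      sect <- retinal_sectors()
      fmu <- amu * exp(stats::rnorm(nrow(sect), 0, field_cv))
      value <- if (metric == "cell_count") stats::rpois(nrow(sect), fmu)
      else if (metric == "gfap_fraction") pmin(fmu, 1)
      else fmu
      out[[length(out) + 1]] <- tibble::tibble(
        animal_id = paste0(grp, a), group = grp, layer = layer,
        area = sect$area, zone = sect$zone, metric = metric,
        value = as.numeric(value))
    }
  }
  dplyr::bind_rows(out)
}
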