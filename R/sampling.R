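#' Calibrated field area per magnification
#'
#' At 20x one photographed field covers 0.1502 mm^2; at 40x the field area
#' scales by the inverse square of the magnification ratio and is reported
#' rounded to 4 decimals (0.0376 mm^2).
#'
#' @param magnification `"20x"` or `"40x"`.
#' @return Field area in mm^2.
#' @export
field_area_mm2 <- function(magnification) {
  switch(as.character(magnification),
         "20x" = 0.1502,
         "40x" = round(0.1502 / 4, 4),
         stop("unknown magnification: ", magnification))
}

RETINAL_AREAS <- c("superior", "inferior", "nasal", "temporal")
RETINAL_ZONES <- c("peripapillary", "intermediate", "peripheral")

#' The 12 sectors of the whole-mount sampling geometry
#'
#' @return Tibble of the 4 areas x 3 zones = 12 (area, zone) sectors.
#' @export
retinal_sectors <- function() {
  tidyr::expand_grid(area = RETINAL_AREAS, zone = RETINAL_ZONES)
}

#' Assign a point to its retinal sector
#'
#' Maps a point given relative to the optic-disc centre to one of the 12
#' sectors: the area is the quadrant about the diagonal meridians (up =
#' superior, down = inferior; the horizontal directions map to nasal or
#' temporal depending on eye laterality), and the zone is determined by
#' radial distance in equal thirds of the retinal radius, with half-open
#' breaks (`[0, R/3)` peripapillary, `[R/3, 2R/3)` intermediate,
#' `[2R/3, R]` peripheral).
#'
#' @param x,y Coordinates relative to the optic-disc centre; `+y` is
#'   superior, `+x` is the anatomically right-hand side of the image.
#' @param retina_radius Optic-disc-to-periphery distance, same units.
#' @param eye `"right"` (default) or `"left"`; on a right eye `+x` maps to
#'   nasal, on a left eye to temporal.
#' @param zone_breaks Fractions of the radius splitting the zones
#'   (default equal thirds).
#' @return A one-row tibble with `area` and `zone`.
#' @export
assign_region <- function(x, y, retina_radius, eye = "right",
                          zone_breaks = c(1 / 3, 2 / 3)) {
  r <- sqrt(x^2 + y^2)
  if (r > retina_radius) stop("point outside retina")
  ang <- atan2(y, x)   # 0 = +x, pi/2 = up
  quadrant <- if (ang >= pi / 4 && ang < 3 * pi / 4) "superior"
  else if (ang >= -3 * pi / 4 && ang < -pi / 4) "inferior"
  else if (ang >= -pi / 4 && ang < pi / 4) "plus_x"
  else "minus_x"
  area <- switch(quadrant,
    superior = "superior", inferior = "inferior",
    plus_x = if (eye == "right") "nasal" else "temporal",
    minus_x = if (eye == "right") "temporal" else "nasal")
  frac <- r / retina_radius
  zone <- if (frac < zone_breaks[1]) "peripapillary"
  else if (frac < zone_breaks[2]) "intermediate"
  else "peripheral"
  tibble::tibble(area = area, zone = zone)
}

#' Sampling plan for a whole-mount study
#'
#' @param layers Character vector of retinal layers photographed per
#'   sector (e.g. `c("OPL", "IPL", "NFL-GCL")` for the microglial study,
#'   `"NFL-GCL"` for GFAP).
#' @param fields_per_sector Fields photographed per (area, zone) sector.
#' @param magnification Objective used.
#' @return A `sampling_plan` list with `n_areas = 4`, `n_zones = 3`.
#' @export
sampling_plan <- function(layers = c("OPL", "IPL", "NFL-GCL"),
                          fields_per_sector = 1,
                          magnification = "20x") {
  stopifnot(length(layers) >= 1, fields_per_sector >= 1)
  structure(list(n_areas = 4L, n_zones = 3L, layers = layers,
                 fields_per_sector = as.integer(fields_per_sector),
                 magnification = magnification),
            class = "sampling_plan")
}

#' Enumerate every field of a sampling plan
#'
#' Expands the plan over retinas and reports the printed design totals:
#' 12 sectors per retina, sectors x layers fields per retina, and the
#' per-group total.
#'
#' @param plan A [sampling_plan()].
#' @param n_retinas_per_group Retinas per experimental group (default 6).
#' @param groups Group labels (default WT and DS).
#' @return A list with `inventory` (tibble: group, retina, layer, area,
#'   zone, field), `sectors_per_retina`, `fields_per_retina`,
#'   `fields_per_group`, `fields_total`.
#' @export
plan_fields <- function(plan, n_retinas_per_group = 6,
                        groups = c("WT", "DS")) {
  stopifnot(inherits(plan, "sampling_plan"))
  inv <- tidyr::expand_grid(
    group = groups,
    retina = seq_len(n_retinas_per_group),
    layer = plan$layers,
    retinal_sectors(),
    field = seq_len(plan$fields_per_sector))
  sectors <- plan$n_areas * plan$n_zones
  per_retina <- sectors * length(plan$layers) * plan$fields_per_sector
  list(inventory = inv,
       sectors_per_retina = sectors,
       fields_per_retina = per_retina,
       fields_per_group = per_retina * n_retinas_per_group,
       fields_total = per_retina * n_retinas_per_group * length(groups))
}

#' Aggregate field measurements into per-group summaries
#'
#' Field-level values are first averaged within each retina (and stratum),
#' so the animal is the experimental unit, and then summarized per group
#' (and stratum) as mean, sample SD (n - 1 denominator) and n. For the
#' `total` stratification all 12 sectors of a retina are pooled before
#' averaging across retinas.
#'
#' @param measurements Tibble with columns `animal_id`, `group`, `value`
#'   and (for stratified summaries) `area` and/or `zone`. One metric at a
#'   time.
#' @param stratification `"total"`, `"by_area"` or `"by_zone"`.
#' @param unit `"animal"` (default; average fields within retina first) or
#'   `"field"` (treat each field as an observation).
#' @return Tibble with grouping columns, `mean`, `sd`, `n`; strata with a
#'   single observation carry `sd = NA`.
#' @export
aggregate_measurements <- function(measurements,
                                   stratification = c("total", "by_area",
                                                      "by_zone"),
                                   unit = c("animal", "field")) {
  stratification <- match.arg(stratification)
  unit <- match.arg(unit)
  if (nrow(measurements) == 0) stop("no measurements supplied")
  strat_col <- switch(stratification, total = character(),
                      by_area = "area", by_zone = "zone")
  if (unit == "animal") {
    obs <- measurements |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("group", "animal_id", strat_col)))) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  } else obs <- measurements
  obs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("group", strat_col)))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n = dplyr::n(), .groups = "drop")
}
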