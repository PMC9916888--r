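# retinaglia

Quantification of glial activation in fluorescence micrographs of
retinal whole-mounts.

Whole-mount preparations allow en-face imaging of entire retinal cell
plexuses. Glial activation leaves measurable morphological signatures:
microglia retract their processes (smaller **arbor area**, the area of
the polygon spanning the most distal process tips), thicken their somas
and processes (larger **occupied area**, the area of positive staining
per cell) and may proliferate; reactive astrocytes increase the
**GFAP-labelled retinal area** (GFAP-RA), the fraction of a field
positive for GFAP. This package implements the complete measurement
chain for such studies, for researchers quantifying glial and neuronal
populations in whole-mounts (e.g. in models of neurological disease):

- **Automatic cell counting**: average a z-stack to a projection,
  normalize to the image maximum, zero pixels below a threshold
  fraction *t* (default 0.2), segment connected components, take one
  intensity-weighted centre of mass per component, and merge centroids
  closer than a minimum distance *d*ₘᵢₙ by single-linkage so each cell
  is counted once. The count is invariant to uniform intensity
  rescaling and non-increasing in *d*ₘᵢₙ.
- **Per-cell morphometrics**: occupied area = |component| · Δx² (Δx =
  pixel size); arbor area = pixel count of the component's convex hull.
- **Area-fraction measurement**: GFAP-RA = foreground / total pixels
  after per-field Otsu (or fixed) thresholding.
- **Sampling geometry**: the 4 areas (superior, inferior, nasal,
  temporal) × 3 zones (peripapillary, intermediate, peripheral) = 12
  sectors of the whole-mount design, field-area calibration (0.1502 mm²
  at 20×, 0.0376 mm² at 40×), and animal-level aggregation.
- **Statistics**: Shapiro–Wilk and Levene screening, two-way ANOVA
  (group × stratum, Type II), Tukey post hoc gated on the omnibus F,
  and star annotation (`*` p < 0.05 … `****` p < 0.0001).
- **Synthetic data with exact ground truth**: hard-core-placed ramified
  microglia, honeycomb astrocyte plexuses with controllable coverage,
  and Gaussian nuclei fields, plus whole simulated WT-vs-DS cohorts
  with programmable effect sizes — used to validate every stage.

## Worked example

Simulate a small two-group cohort with programmed disease effects
(microglial process retraction in the OPL, a 1.4× astroglial coverage
increase), run the full pipeline, and inspect the statistics:

```r
library(retinaglia)

ch <- cohort_spec(
  n_per_group = 3,
  plan = sampling_plan(layers = c("OPL", "GFAP")),
  base_spec = field_spec(image_shape = c(192, 192), n_cells = 5,
                         min_spacing_px = 45, process_length_px = 20),
  effect_sizes = list(OPL = list(process_length = 0.7), coverage = 1.4),
  gfap_target_coverage = 0.25, seed = 42)

res <- run_pipeline(ch, params = counting_params(min_distance_px = 12))

aggregate_measurements(subset(res$measurements,
                              metric == "gfap_fraction"), "total")
#> # A tibble: 2 × 4
#>   group  mean      sd     n
#>   <chr> <dbl>   <dbl> <int>
#> 1 DS    0.350 0.00430     3
#> 2 WT    0.248 0.00381     3

res$stats$arbor_area_mm2$by_area$anova$table
#> # A tibble: 3 × 4
#>   effect        df      F         p
#>   <chr>      <dbl>  <dbl>     <dbl>
#> 1 group          1 34.8   0.0000225
#> 2 area           3  0.864 0.480
#> 3 group:area     3  1.38  0.286

res$stats$arbor_area_mm2$by_area$posthoc[, c("stratum", "diff",
                                             "p_adj", "stars")]
#> # A tibble: 4 × 4
#>   stratum      diff   p_adj stars
#>   <chr>       <dbl>   <dbl> <chr>
#> 1 inferior 0.000419 0.00609 **
#> 2 nasal    0.000238 0.230   ns
#> 3 superior 0.000267 0.138   ns
#> 4 temporal 0.000162 0.654   ns
```

Reading the output: the measured GFAP fraction rises from 0.248 (WT) to
0.350 (DS) — recovering the programmed 1.4× coverage effect. The
two-way ANOVA on arbor area finds a strong group effect
(p = 2.3 × 10⁻⁵): DS arbor areas are smaller, the programmed process
retraction. The Tukey table shows the per-area WT−DS differences
(positive `diff` = smaller DS arbor); at n = 3 per group only the
largest per-area contrast survives adjustment — single-stratum contrasts
at this tiny n are underpowered, which is why the study design uses 6
animals per group.

A thin command-line front end over the same functions is installed at
`inst/cli/retinaglia` (subcommands `simulate`, `count`, `run`).

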