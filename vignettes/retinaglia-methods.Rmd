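---
title: "Quantifying glial activation in retinal whole-mounts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial activation in retinal whole-mounts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaglia)
```

## The problem

Retinal whole-mounts allow en-face imaging of entire cell plexuses —
microglia in the outer and inner plexiform layers (OPL, IPL) and the
nerve fiber layer–ganglion cell layer (NFL-GCL), astrocytes in the
NFL-GCL, and neuronal populations such as Brn3a+ retinal ganglion cells
and GAD65/67+ amacrine cells. Glial activation leaves morphological
signatures: microglia retract their processes (a smaller *arbor area*),
thicken their somas and processes (a larger *occupied area*) and may
proliferate (higher counts); reactive astrocytes expand the fraction of
retina covered by GFAP-positive labelling (GFAP-RA). This package
implements the full quantification chain for such studies — automatic
cell counting, per-cell morphometrics, labelled-area fraction, the
regional sampling geometry, and the group-comparison statistics — along
with a synthetic image generator carrying exact ground truth, so every
stage can be validated without access to microscope data.

## The counting algorithm

`count_cells()` composes five operations, each exported separately:

1. **z-projection** (`z_project`): pixelwise arithmetic mean over the
   planes of a z-stack (a max-based extended-focus-style projection is
   available as an option).
2. **normalization** (`normalize_max`): division by the image maximum so
   values span [0, 1]. This makes the whole pipeline invariant to
   uniform intensity rescaling of the input.
3. **threshold suppression** (`threshold_suppress`): pixels strictly
   below a fraction of the maximum (default 0.2) are zeroed; surviving
   pixels keep their values. The inequality is deliberately strict.
4. **segmentation** (`segment_nonzero`): connected components of the
   surviving pixels. The default adjacency is 8-connected so that thin
   diagonal processes do not fragment a cell; 4-connectivity is
   available. One intensity-weighted centre of mass per component is
   computed at subpixel precision (`centers_of_mass`; a geometric
   centroid is an option).
5. **minimum-distance merging** (`merge_min_distance`): centroids
   strictly closer than `min_distance_px` are considered the same cell.
   Because "closer than" is a pairwise relation, we take its transitive
   closure — single-linkage clustering, implemented as union–find — so
   the result is independent of point order. Each cluster is represented
   by the unweighted mean of its member points and counted once.

The merge radius is the one genuinely free parameter: published
protocols leave its numeric value to the operator. We expose it as a
required setting with a documented heuristic default of 0.8 times the
expected soma diameter in pixels. Counts are non-increasing in the merge
radius, which the test suite asserts as a property.

## Per-cell morphometrics

Both metrics operate on a binarized field (`binarize_field`), default
Otsu per field — manual brightness/contrast adjustment followed by
manual thresholding is not reproducible, and Otsu is the standard
automatic surrogate; a fixed threshold is available for strict reruns,
and the method and cut actually used are recorded on the mask.

- **Occupied area** (`occupied_cell_area`): the pixel count of the
  connected foreground component containing a seed point, converted to
  mm² via `pixel_size_um² · 10⁻⁶`. A cell is one connected component;
  fragments disconnected by thresholding are not chased.
- **Arbor area** (`arbor_area`): the area of the polygon spanning the
  most distal processes, formalized as the convex hull of the cell's
  component. We report the number of pixel centres inside or on the
  hull — what an image-analysis polygon ROI measures — rather than the
  shoelace area of the hull vertices. This choice guarantees
  `arbor_area ≥ occupied_area` for every cell including compact convex
  ones (the shoelace polygon through boundary pixel centres of a filled
  disk is *smaller* than its pixel count), at the cost of a rasterization
  bias of order perimeter/area. A manually drawn polygon may be concave
  and therefore smaller than the hull; the hull is the reproducible
  formalization and this positive bias is a known property.

`sample_cells_for_morphometry()` implements the protocol of measuring
three randomly selected *whole* cells per field: only components that do
not touch the outermost row or column are eligible, and the draw is
seeded.

## GFAP-labelled retinal area

`gfap_retinal_area()` is the area-fraction measurement: foreground
pixels after binarization over total pixels, with absolute areas in mm²
through the calibration. The threshold used by the original MATLAB
protocol is unpublished, so Otsu is the default and the applied
threshold is recorded in the result.

## Sampling geometry and aggregation

The whole-mount design divides each retina into 4 areas (superior,
inferior, nasal, temporal) × 3 concentric zones (peripapillary,
intermediate, peripheral) = 12 sectors; one field per sector per layer.
Three microglial plexuses give 36 fields/retina and 216 per group of 6;
a single astrocyte layer gives 72 fields per study. `plan_fields()`
reproduces this arithmetic; `field_area_mm2()` encodes the calibrated
field areas (0.1502 mm² at 20×, 0.0376 mm² at 40×, the latter being the
20× area scaled by the inverse square of the magnification ratio and
rounded to 4 decimals).

`assign_region()` maps a point relative to the optic disc to its sector.
The published schematic draws but does not dimension the zones, so we
use equal thirds of the disc-to-periphery distance with half-open breaks
([0, R/3) peripapillary, [R/3, 2R/3) intermediate, the rest peripheral);
the break fractions are configurable. Nasal/temporal assignment depends
on eye laterality, which must come from metadata; the default assumes a
right eye.

`aggregate_measurements()` treats the **animal as the experimental
unit**: field values are averaged within retina (and stratum) before
group means, sample SDs and n are computed. A field-level mode exists
for exploration but the animal-level default is the conservative choice
for inference.

## Statistics battery

`screen_assumptions()` runs Shapiro–Wilk per group (requiring n ≥ 3) and
Levene's test across groups. `two_way_anova()` fits
`value ~ group * stratum` and reports Type II F tests by default — exact
for the balanced designs produced by the sampling plan and robust to the
mild imbalance left by excluded fields (Type I/III selectable). A failed
Levene screen produces a warning, not an automatic switch to
nonparametric tests. `tukey_posthoc()` is gated: it refuses to run
unless some omnibus F reached p < 0.05, and then reports Tukey-adjusted
pairwise comparisons (by default the WT-vs-DS contrast within each
stratum) with star labels mapped strictly:
`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.

Whether stratified panels should come from one ANOVA with stratum as a
factor or from separate per-stratum ANOVAs is ambiguous in most
published protocols; `compare_groups()` implements both (`mode =
"pooled"` or `"per_stratum"`) and records the mode in its output.

## The synthetic generator

The generator is first-class, tested code. It produces three field
types, all with hard-core (minimum-spacing) centre placement by
rejection sampling with a bounded retry budget (default 10 000; an
infeasible density raises an error rather than silently under-placing):

- **Microglia fields**: filled soma disks with Poisson-distributed
  numbers of primary processes drawn as random-direction two-segment
  polylines, with a probabilistic secondary branch — enough to reproduce
  ramified vs. retracted morphology with one length parameter.
- **Astrocyte fields**: a jittered hexagonal (honeycomb) network of
  somata joined by processes. Coverage is controlled through the
  Euclidean distance transform of the 1-px network skeleton: because
  lattice distances are heavily tied, a uniform sub-pixel dither
  (U(0, 0.25)) is added before thresholding, which makes coverage
  respond continuously to process thickness and lets a requested
  coverage fraction be matched essentially exactly by a quantile cut.
- **Nuclei fields**: Gaussian-profile blobs (σ = soma radius / 1.5) with
  unit peaks, emulating nuclear/somatic labelling for count validation.

Intensities are background + signal with additive Gaussian noise clipped
to [0, 1] (default background 0.05, noise SD 0.02 — the spec constructor
enforces that ≥ 99% of background pixels stay below the downstream 0.2
detection threshold). Images carry no pixel-size or dimension values
from any published study: the defaults (512² px at 0.757 µm/px, i.e. a
0.1502 mm² field) are this package's own documented choices.

Ground truth records every centre, per-cell pixel mask, the convex-hull
arbor area of each mask (same operational definition as the
morphometry), and the exact labelled-coverage fraction. For astrocyte
fields per-cell masks are not recorded — a Voronoi split of a honeycomb
network is not guaranteed to produce connected per-cell masks — and the
coverage fraction is the measurand.

`simulate_cohort()` expands a sampling plan over animals and sectors
with per-field seeds derived deterministically from the cohort seed, and
applies multiplicative DS effect factors (optionally per layer) to the
DS group's field specs. Astrocyte fields draw their per-field coverage
target from a lognormal jitter (CV 0.10, `gfap_coverage_cv`) around the
group mean: the quantile-matched generator would otherwise hit its
target exactly in every field, and zero within-group variance is both
unrealistic for stained tissue and degenerate for the ANOVA. `simulate_measurements()` draws per-field metric
values directly from the hierarchical distributional model the image
generator realizes — lognormal field noise (CV 0.18) around the metric
baseline, Poisson for counts, with the DS mean scaled by the effect
implied by the parameter factors (arbor ∝ length², occupied ∝
thickness · length · soma, coverage and counts directly). By default
there is **no shared animal random effect** (`animal_cv = 0`), matching
the image generator in which every field is an independent draw given
its group's parameters; a positive `animal_cv` emulates between-retina
heterogeneity, but then the fixed-effects ANOVA is anticonservative
because strata within an animal become correlated — mixed models are
deliberately out of scope.

Baselines for the measurement model (50 cells/field, arbor
3.5 × 10⁻³ mm², occupied 5 × 10⁻⁴ mm², GFAP fraction 0.30) are plausible
magnitudes for retinal plexuses at the 20× calibration, chosen once and
documented here rather than taken from any dataset.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: bright
compact somata with thin processes, hard-core spacing, controllable
labelled-area fraction, programmable group effects, sub-threshold
background. It does **not** model the optics (no PSF or
optical-sectioning simulation), vessels, Müller glia, uneven
illumination, staining artefacts or touching/overlapping somata. Passing
tests therefore demonstrate correctness of the measurement chain on
images satisfying the stated assumptions, not robustness to every
real-microscopy artefact.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise each property at
meaningful scale: segmentation and merging are checked against
brute-force flood-fill and transitive-closure oracles on 200 random
images up to 32 × 32; count recovery on 50 simulated nuclei fields of
100 hard-core blobs each (360² px — at 256² the packing fraction of a
20 px hard core sits at the random-sequential-adsorption jamming limit);
type-I error on 500 null cohorts of 6 vs 6 animals; power on 200 cohorts
with a programmed 40% arbor reduction; and direction-of-effect
reproduction (arbor down in OPL, occupied up in IPL, GFAP coverage up)
on 20 cohorts. The statistical calibrations run on the measurement-level
model; the image-rendering path is exercised end to end by the
integration test of `run_pipeline()` and by the count-recovery and
morphometry checks.

## Known limitations

- The hull-based arbor area is biased upward relative to a concave
  manual polygon and by rasterization for small cells.
- Automatic counting of microglia fields is an extension: ramified cells
  whose processes touch can merge into one component, so counts on dense
  microglial plexuses undercount relative to a human observer; the
  original protocol counted microglia manually (externally supplied
  points flow through the same detection type).
- The Otsu default makes per-field thresholds data-dependent; for strict
  reproduction of a fixed-threshold protocol use `method = "fixed"`.
- Separate ANOVAs are run per metric and stratification with no
  correction across metrics beyond Tukey's adjustment within a family.
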