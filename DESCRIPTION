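Package: retinaglia
Title: Quantification of Glial Activation in Retinal Whole-Mounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible quantification of fluorescence micrographs of
    retinal whole-mounts: automatic cell counting by intensity
    normalization, thresholding, connected-component segmentation and
    minimum-distance merging of segment centroids; per-cell microglial
    morphometrics (occupied area and convex-hull arbor area); labelled
    retinal-area fraction for astroglial (GFAP) staining; the regional
    sampling geometry of whole-mount studies (four areas by three
    concentric zones); and group-comparison statistics (Shapiro-Wilk and
    Levene screening, two-way ANOVA with Tukey post hoc tests and
    significance-star annotation). Includes a synthetic field and cohort
    generator with exact ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    car,
    grDevices,
    stats,
    utils,
    pracma,
    withr,
    tibble,
    dplyr,
    tidyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
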