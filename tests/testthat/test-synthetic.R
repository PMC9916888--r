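test_that("field specs enforce their invariants", {
  expect_error(field_spec(n_cells = 5, min_spacing_px = 6,
                          soma_radius_px = 4), "min_spacing")
  expect_error(field_spec(background_level = 0.15, noise_sd = 0.05),
               "threshold")
  expect_silent(field_spec(n_cells = 0))
})

test_that("empty and deterministic generation behave as specified", {
  sp <- field_spec(image_shape = c(96, 96), n_cells = 0, seed = 3)
  sim <- simulate_microglia_field(sp)
  expect_equal(nrow(sim$truth$cell_centers), 0)
  expect_equal(sim$truth$true_coverage_fraction, 0)
  expect_lt(max(sim$image$pixels), 0.2)   # background stays subthreshold
  sp2 <- field_spec(image_shape = c(128, 128), n_cells = 4,
                    min_spacing_px = 40, process_length_px = 20, seed = 17)
  a <- simulate_microglia_field(sp2)
  b <- simulate_microglia_field(sp2)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("hard-core placement respects the minimum spacing and signals infeasibility", {
  sp <- field_spec(image_shape = c(512, 512), n_cells = 25,
                   min_spacing_px = 60, seed = 8)
  sim <- simulate_microglia_field(sp)
  ctr <- sim$truth$cell_centers
  expect_equal(nrow(ctr), 25)
  d <- as.matrix(dist(ctr)); diag(d) <- Inf
  expect_gte(min(d), 60)
  too_dense <- field_spec(image_shape = c(64, 64), n_cells = 60,
                          min_spacing_px = 20, soma_radius_px = 2,
                          process_length_px = 5, seed = 1)
  expect_error(simulate_microglia_field(too_dense), "infeasible")
})

test_that("microglia ground truth is connected and coverage bookkeeping is exact", {
  sp <- field_spec(image_shape = c(160, 160), n_cells = 4,
                   min_spacing_px = 50, process_length_px = 25, seed = 21)
  sim <- simulate_microglia_field(sp)
  for (px in sim$truth$cell_pixels) {
    m <- matrix(0, 160, 160); m[px] <- 1
    expect_equal(max(segment_nonzero(m, 8)), 1)
  }
  union_px <- unique(unlist(sim$truth$cell_pixels))
  expect_equal(sim$truth$true_coverage_fraction,
               length(union_px) / (160 * 160))
})

test_that("astrocyte coverage hits its target and zero-coverage is blank", {
  sp <- field_spec(image_shape = c(192, 192), n_cells = 25,
                   min_spacing_px = 10, seed = 5)
  blank <- simulate_astrocyte_field(sp, target_coverage = 0)
  expect_equal(blank$truth$true_coverage_fraction, 0)
  expect_false(any(blank$mask))
  for (tc in c(0.15, 0.30, 0.50)) {
    sim <- simulate_astrocyte_field(sp, target_coverage = tc)
    expect_lt(abs(sim$truth$true_coverage_fraction - tc), 0.02)
    expect_equal(sim$truth$true_coverage_fraction, mean(sim$mask))
  }
  expect_error(simulate_astrocyte_field(sp, target_coverage = 0.95),
               "target_coverage")
})

test_that("nuclei fields place exact blobs with unit peaks", {
  sp <- field_spec(image_shape = c(64, 64), n_cells = 1,
                   min_spacing_px = 20, soma_radius_px = 3, noise_sd = 0,
                   seed = 2)
  sim <- simulate_nuclei_field(sp, centers = matrix(c(32, 32), 1))
  expect_equal(nrow(sim$truth$cell_centers), 1)
  expect_equal(max(sim$image$pixels), 1)
  expect_equal(which(sim$image$pixels == 1),
               (32 - 1) * 64 + 32)   # peak at the requested centre
  big <- simulate_nuclei_field(tiny_nuclei_spec(12))
  expect_equal(nrow(big$truth$cell_centers), 100)
  d <- as.matrix(dist(big$truth$cell_centers)); diag(d) <- Inf
  expect_gte(min(d), 20)
})

test_that("cohort structure matches the sampling design and derives per-field seeds", {
  ch <- cohort_spec(
    n_per_group = 1,
    plan = sampling_plan(layers = "OPL"),
    base_spec = field_spec(image_shape = c(96, 96), n_cells = 2,
                           min_spacing_px = 30, process_length_px = 12),
    seed = 6)
  sim <- simulate_cohort(ch)
  expect_equal(nrow(sim$index), 24)            # 12 sectors x 2 retinas
  expect_equal(sum(sim$index$group == "WT"), 12)
  expect_equal(length(unique(sim$index$seed)), 24)
  expect_true(all(sim$index$seed < 2^31 & sim$index$seed >= 0))
  # null effects: WT and DS field specs are identical by construction
  eff <- retinaglia:::effects_for_layer(list(), "OPL")
  expect_identical(retinaglia:::scale_spec(ch$base_spec, eff), ch$base_spec)
})

test_that("programmed process retraction lowers DS ground-truth arbor areas", {
  ch <- cohort_spec(
    n_per_group = 2,
    plan = sampling_plan(layers = "OPL"),
    base_spec = field_spec(image_shape = c(128, 128), n_cells = 3,
                           min_spacing_px = 40, process_length_px = 18),
    effect_sizes = list(process_length = 0.7),
    seed = 31)
  sim <- simulate_cohort(ch)
  arbors <- sapply(seq_len(nrow(sim$index)), function(i)
    mean(sim$fields[[i]]$truth$true_arbor_area_px))
  grp <- sim$index$group
  expect_lt(mean(arbors[grp == "DS"]), mean(arbors[grp == "WT"]))
})
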