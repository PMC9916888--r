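test_that("binarization: fixed cut, Otsu recovery, degenerate input", {
  m <- matrix(c(0.4, 0.6, 0.4, 0.6), 2, 2)
  mask <- binarize_field(m, "fixed", 0.5)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(mask, "threshold"), 0.5)
  expect_false(any(binarize_field(matrix(0.1, 4, 4), "fixed", 0.5)))
  expect_error(binarize_field(matrix(0.3, 4, 4), "otsu"), "constant")
  # bimodal image: Otsu recovers the constructed mask exactly
  set.seed(2)
  truth <- matrix(runif(64 * 64) < 0.2, 64, 64)
  img <- ifelse(truth, 0.8, 0.05) + rnorm(64 * 64, 0, 0.01)
  img <- matrix(pmin(pmax(img, 0), 1), 64, 64)
  expect_identical(unname(binarize_field(img, "otsu")[, ]), truth)
})

test_that("occupied area counts the seeded component in calibrated units", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(occupied_cell_area(one, c(3, 3), 1), 1e-6)
  d <- disk_mask(20)
  ctr <- (nrow(d) + 1) / 2
  # brute-force rasterized pixel count is the oracle for the disk
  expect_equal(occupied_cell_area(d, c(ctr, ctr), 1), sum(d) * 1e-6)
  expect_lt(abs(sum(d) - pi * 20^2) / (pi * 20^2), 0.02)
  # two disjoint cells: only the seeded one is measured
  two <- matrix(FALSE, 20, 20)
  two[2:4, 2:4] <- TRUE; two[10:15, 10:15] <- TRUE
  expect_equal(occupied_cell_area(two, c(3, 3), 1), 9e-6)
  expect_error(occupied_cell_area(two, c(7, 7), 1), "background")
})

test_that("arbor area is the convex-hull span and dominates occupied area", {
  L <- 50
  cr <- cross_mask(L)
  ctr <- as.integer((nrow(cr) + 1) / 2)
  got_px <- arbor_area(cr, c(ctr, ctr), 1) * 1e6
  # lattice-point oracle: integer points with |dr| + |dc| <= L
  oracle <- sum(outer(-L:L, -L:L, function(i, j) abs(i) + abs(j) <= L))
  expect_equal(got_px, oracle)
  expect_lt(abs(got_px - 2 * L^2) / (2 * L^2), 0.03)  # analytic 2L^2
  # convex component: hull adds nothing beyond rasterization
  d <- disk_mask(15)
  c0 <- (nrow(d) + 1) / 2
  occ <- occupied_cell_area(d, c(c0, c0), 1)
  arb <- arbor_area(d, c(c0, c0), 1)
  expect_gte(arb, occ)
  expect_lt((arb - occ) / occ, 0.01)
})

test_that("morphometry is robust to 90-degree rotation", {
  sim <- simulate_microglia_field(
    field_spec(image_shape = c(180, 180), n_cells = 1, min_spacing_px = 60,
               process_length_px = 30, seed = 9))
  mask <- matrix(FALSE, 180, 180)
  mask[sim$truth$cell_pixels[[1]]] <- TRUE
  seed_pt <- round(sim$truth$cell_centers[1, ])
  rot <- t(mask[nrow(mask):1, ])
  seed_rot <- c(seed_pt[2], nrow(mask) + 1 - seed_pt[1])
  expect_equal(occupied_cell_area(rot, seed_rot, 1),
               occupied_cell_area(mask, seed_pt, 1))
  a1 <- arbor_area(mask, seed_pt, 1)
  a2 <- arbor_area(rot, seed_rot, 1)
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("cell sampling draws whole (non-border) cells reproducibly", {
  mask <- matrix(FALSE, 40, 40)
  centers <- expand.grid(row = c(6, 16, 26, 36), col = c(6, 16, 26))
  for (i in seq_len(nrow(centers)))
    mask[centers$row[i] + (-1:1), centers$col[i] + (-1:1)] <- TRUE
  # the row-36 cells sit near but not on the border; add one touching cell
  mask[1, 20:22] <- TRUE
  det <- tibble::tibble(row = centers$row, col = centers$col)
  s1 <- sample_cells_for_morphometry(mask, det, n = 3, seed = 4)
  s2 <- sample_cells_for_morphometry(mask, det, n = 3, seed = 4)
  expect_identical(s1, s2)
  expect_false(any(s1$row == 1))
  # demanding more cells than exist off the border errors
  expect_error(sample_cells_for_morphometry(mask, det, n = 13, seed = 1),
               "non-border")
  border_only <- matrix(FALSE, 10, 10); border_only[1, 4:6] <- TRUE
  expect_error(sample_cells_for_morphometry(
    border_only, tibble::tibble(row = 1, col = 5), n = 1, seed = 1),
    "non-border")
})

test_that("labelled-area fraction is exact on constructed masks", {
  m <- matrix(0, 50, 40)
  m[1:15, ] <- 1   # exactly 30% of 50 rows... 15/50 of pixels
  img <- field_image(m, pixel_size_um = 2)
  res <- gfap_retinal_area(img, method = "fixed", threshold = 0.5)
  expect_equal(res$fraction, 0.30)
  expect_equal(res$labelled_area_mm2, 0.30 * res$field_area_mm2)
  expect_equal(res$field_area_mm2, 50 * 40 * 4 * 1e-6)
  blank <- field_image(matrix(0, 20, 20), pixel_size_um = 1)
  expect_equal(gfap_retinal_area(blank, "fixed", 0.5)$fraction, 0)
})

test_that("programmed astroglial reactivity raises the measured fraction", {
  wins <- 0L
  for (s in 1:20) {
    sp <- field_spec(image_shape = c(128, 128), n_cells = 12,
                     min_spacing_px = 9, process_thickness_px = 2, seed = s)
    wt <- simulate_astrocyte_field(sp)
    sp_ds <- sp; sp_ds$process_thickness_px <- 2 * 1.4
    ds <- simulate_astrocyte_field(sp_ds)
    fwt <- gfap_retinal_area(wt$image, "fixed", 0.4)$fraction
    fds <- gfap_retinal_area(ds$image, "fixed", 0.4)$fraction
    wins <- wins + (fds > fwt)
  }
  expect_gte(wins, 19)
})
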