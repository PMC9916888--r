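test_that("z-projection averages planes and enforces shape agreement", {
  a <- matrix(0.2, 4, 4)
  b <- matrix(0.6, 4, 4)
  expect_identical(z_project(a), a)
  expect_equal(z_project(list(a, b)), matrix(0.4, 4, 4))
  expect_equal(z_project(list(a, b), method = "max"), matrix(0.6, 4, 4))
  expect_error(z_project(list(a, matrix(0, 3, 4))), "shape mismatch")
  expect_error(z_project(list()), "empty")
})

test_that("normalization scales to max 1, preserves order, rejects zeros", {
  expect_equal(normalize_max(matrix(200, 3, 3)), matrix(1, 3, 3))
  m <- matrix(c(0, 50, 100, 0), 2, 2)
  expect_equal(normalize_max(m), m / 100)
  expect_error(normalize_max(matrix(0, 2, 2)), "all-zero")
})

test_that("threshold suppression zeroes strictly-below pixels and is idempotent", {
  m <- matrix(c(0.1, 0.2, 0.5, 0.9), 2, 2)
  out <- threshold_suppress(m, 0.2)
  expect_equal(as.vector(out), c(0, 0.2, 0.5, 0.9))
  expect_equal(threshold_suppress(out, 0.2), out)
  all_above <- matrix(c(0.3, 0.4, 0.5, 0.6), 2, 2)
  expect_equal(threshold_suppress(all_above, 0.2), all_above)
  expect_error(threshold_suppress(m, 1.2), "threshold")
})

test_that("segmentation separates blobs and respects connectivity", {
  blank <- matrix(0, 8, 8)
  expect_equal(max(segment_nonzero(blank)), 0)
  two <- matrix(0, 8, 8)
  two[2:3, 2:3] <- 1; two[6:7, 6:7] <- 1
  expect_equal(max(segment_nonzero(two, 8)), 2)
  expect_equal(max(segment_nonzero(two, 4)), 2)
  diag2 <- matrix(0, 5, 5)
  diag2[2, 2] <- 1; diag2[3, 3] <- 1   # touch only at a corner
  expect_equal(max(segment_nonzero(diag2, 8)), 1)
  expect_equal(max(segment_nonzero(diag2, 4)), 2)
})

test_that("centres of mass are intensity-weighted, subpixel", {
  m <- matrix(0, 12, 25)
  m[10, 20] <- 0.7
  cm <- centers_of_mass(segment_nonzero(m), m)
  expect_equal(cm$row, 10)
  expect_equal(cm$col, 20)
  # two equal pixels bridged into one segment by an equal middle pixel
  m2 <- matrix(0, 3, 5)
  m2[1, 1:3] <- c(1, 1, 2)
  cm2 <- centers_of_mass(segment_nonzero(m2), m2)
  expect_equal(cm2$col, (1 * 1 + 2 * 1 + 3 * 2) / 4)  # hand-computed 2.25
  expect_equal(cm2$n_pixels, 3L)
  # geometric option ignores intensity
  cm3 <- centers_of_mass(segment_nonzero(m2), m2, weight = "geometric")
  expect_equal(cm3$col, 2)
})

test_that("minimum-distance merging is strict, single-linkage, order-independent", {
  two_close <- tibble::tibble(row = c(0, 3), col = c(0, 0))
  expect_equal(nrow(merge_min_distance(two_close, 5)), 1)
  at_limit <- tibble::tibble(row = c(0, 5), col = c(0, 0))
  expect_equal(nrow(merge_min_distance(at_limit, 5)), 2)  # strict "closer"
  chain <- tibble::tibble(row = c(0, 0, 4, 8), col = 0)   # gaps 0, 4, 4
  res <- merge_min_distance(chain, 5)
  expect_equal(nrow(res), 1)
  expect_equal(res$row, mean(chain$row))
  # order independence: shuffled input gives the same representative set
  set.seed(11)
  pts <- tibble::tibble(row = runif(30, 0, 50), col = runif(30, 0, 50))
  a <- merge_min_distance(pts, 8)
  b <- merge_min_distance(pts[sample(30), ], 8)
  expect_equal(dplyr::arrange(a[c("row", "col")], row, col),
               dplyr::arrange(b[c("row", "col")], row, col))
})

test_that("merging matches the all-pairs transitive-closure oracle", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(2:25, 1)
    pts <- tibble::tibble(row = runif(n, 0, 40), col = runif(n, 0, 40),
                          segment = seq_len(n))
    min_d <- runif(1, 1, 15)
    expect_true(same_partition(
      merge_partition(pts, min_d),
      bf_cluster(cbind(pts$row, pts$col), min_d)))
  }
})

test_that("segmentation matches a brute-force flood fill on random images", {
  for (s in 1:40) {
    set.seed(s)
    nr <- sample(4:32, 1); nc <- sample(4:32, 1)
    fg <- matrix(runif(nr * nc) < 0.35, nr, nc)
    for (conn in c(4, 8)) {
      expect_identical(canon_labels(segment_nonzero(fg * 1, conn)),
                       canon_labels(bf_label(fg, conn)))
    }
  }
})

test_that("the counting pipeline is scale invariant and monotone in the merge radius", {
  sim <- simulate_nuclei_field(tiny_nuclei_spec(5, n_cells = 40))
  img <- sim$image$pixels
  p <- counting_params(min_distance_px = 10)
  base <- count_cells(img, p)
  expect_identical(count_cells(img * 0.5, p)$count, base$count)
  expect_identical(count_cells(img * 3.7, p)$count, base$count)
  expect_equal(count_cells(img * 3.7, p)$detections, base$detections)
  counts <- sapply(c(0, 5, 15, 40, 120),
                   function(d) count_cells(img, counting_params(
                     min_distance_px = d))$count)
  expect_true(all(diff(counts) <= 0))
  expect_equal(count_cells(matrix(0, 16, 16), p)$count, 0L)
})

test_that("blob counts recover the ground truth when spacing exceeds the merge radius", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_nuclei_field(tiny_nuclei_spec(100 + s))
    cc <- count_cells(sim$image, counting_params(min_distance_px = 10))
    hits <- hits + (cc$count == nrow(sim$truth$cell_centers))
  }
  expect_gte(hits, 9)
})
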