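test_that("a uniform box exercises the pure tie-break path", {
  # all intensities equal: seed must be the smallest linear index and each
  # step must add the smallest-index neighbour
  img <- image_volume(array(5, c(4, 4, 2)), c(1, 1, 1))
  box <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:2))
  sel <- select_brightest_connected(img, box, k = 3, connectivity = 26)
  expect_equal(lin_of(sel, c(4, 4, 2)), c(1, 2, 3))
  # 6-connectivity forbids the diagonal, same outcome along x
  sel6 <- select_brightest_connected(img, box, k = 3, connectivity = 6)
  expect_equal(lin_of(sel6, c(4, 4, 2)), c(1, 2, 3))
})

test_that("selection follows the brightest connected path, not the global top-k", {
  # two bright voxels separated from the seed cluster must be ignored
  arr <- array(0, c(7, 3, 1))
  arr[1, 1, 1] <- 10; arr[2, 1, 1] <- 9; arr[3, 1, 1] <- 1
  arr[6, 1, 1] <- 9.5; arr[7, 1, 1] <- 9.4   # disconnected distractor pair
  img <- image_volume(arr, c(1, 1, 1))
  box <- as.matrix(expand.grid(x = 1:7, y = 1:3, z = 1))
  sel <- select_brightest_connected(img, box, k = 3)
  expect_setequal(lin_of(sel, c(7, 3, 1)), c(1, 2, 3))
})

test_that("greedy output matches the independently coded oracle on random grids", {
  set.seed(42)
  dims <- c(8, 8, 4)
  box <- as.matrix(expand.grid(x = 1:8, y = 1:8, z = 1:4))
  for (conn in c(6, 26)) {
    for (i in 1:100) {
      arr <- array(stats::rnorm(prod(dims)), dims)
      img <- image_volume(arr, c(1, 1, 1))
      sel <- select_brightest_connected(img, box, k = 5,
                                        connectivity = conn)
      expect_identical(lin_of(sel, dims),
                       oracle_brightest_connected(arr, box, 5, conn))
    }
  }
})

test_that("greedy equals the exact connected k-subset search on an easy ridge", {
  # a monotone ridge: the greedy path is provably optimal there
  arr <- array(0, c(5, 4, 2))
  arr[1:4, 2, 1] <- c(8, 7, 6, 5)
  img <- image_volume(arr, c(1, 1, 1))
  box <- as.matrix(expand.grid(x = 1:5, y = 1:4, z = 1:2))
  g <- select_brightest_connected(img, box, k = 3)
  e <- select_brightest_connected_exact(img, box, k = 3)
  expect_setequal(lin_of(g, c(5, 4, 2)), lin_of(e, c(5, 4, 2)))
})

test_that("selection size is k whenever an adequate bright cluster exists", {
  d <- small_lc_design(seed = 2, noise_sigma = 2)
  s <- generate_lc_phantom(d, 1)
  res <- measure_lc(s)
  expect_identical(nrow(res$selected_left), 10L)
  expect_identical(nrow(res$selected_right), 10L)
  expect_true(res$qc$left_valid && res$qc$right_valid)
})

test_that("selected sets are connected and inside their boxes on noisy phantoms", {
  d <- small_lc_design(n_per_group = c(Control = 3), noise_sigma = 3,
                       seed = 5)
  dims <- NULL
  for (i in 1:3) {
    s <- generate_lc_phantom(d, i)
    dims <- dim(s$tse_image$data)
    res <- measure_lc(s)
    for (side in c("left", "right")) {
      qc <- res$qc[[side]]
      expect_true(qc$connected)
      expect_true(qc$inside_box)
      expect_true(qc$centroid_in_box)
    }
  }
})

test_that("noiseless phantoms reproduce the designed contrast ratio", {
  # plateau larger than k: selection is a subset of the uniform plateau
  d <- small_lc_design(noise_sigma = 0, cluster = 20L, seed = 3)
  res <- measure_lc(generate_lc_phantom(d, 1))
  expect_equal(res$lc_i, 1.30, tolerance = 1e-12)
  # plateau of exactly k voxels: selection recovers the truth set exactly
  d10 <- small_lc_design(noise_sigma = 0, cluster = 10L, seed = 3)
  s10 <- generate_lc_phantom(d10, 1)
  res10 <- measure_lc(s10)
  dims <- dim(s10$tse_image$data)
  expect_identical(lin_of(res10$selected_left, dims),
                   lin_of(s10$true_lc_voxels$left, dims))
  expect_equal(res10$lc_i, 1.30, tolerance = 1e-12)
  # contrast formula on the same image
  resc <- measure_lc(s10, formula = "contrast")
  expect_equal(resc$lc_i, 0.30, tolerance = 1e-12)
})

test_that("unit-contrast clusters are invisible: extracted LC-I is ~1", {
  d <- small_lc_design(n_per_group = c(Control = 20), noise_sigma = 1,
                       lc_contrast_by_group = 1.0, seed = 6)
  lci <- vapply(1:20, function(i)
    measure_lc(generate_lc_phantom(d, i))$lc_i, numeric(1))
  # selection of the 10 brightest of ~1450 voxels inflates the mean by a
  # few noise SDs at most (noise is 1% of background here)
  expect_lt(abs(mean(lci) - 1), 0.03)
})

test_that("LC-I is invariant under global rescaling and monotone in LC brightness", {
  d <- small_lc_design(noise_sigma = 2, seed = 7)
  s <- generate_lc_phantom(d, 1)
  base <- measure_lc(s)
  for (f in c(0.5, 42)) {
    s2 <- s
    s2$tse_image$data <- s$tse_image$data * f
    expect_equal(measure_lc(s2)$lc_i, base$lc_i, tolerance = 1e-12)
  }
  # raising every true-LC voxel cannot lower LC-I
  s3 <- s
  dims <- dim(s$tse_image$data)
  for (side in c("left", "right")) {
    lin <- (s$true_lc_voxels[[side]][, 3] - 1) * dims[1] * dims[2] +
      (s$true_lc_voxels[[side]][, 2] - 1) * dims[1] +
      s$true_lc_voxels[[side]][, 1]
    s3$tse_image$data[lin] <- s3$tse_image$data[lin] + 5
  }
  expect_gte(measure_lc(s3)$lc_i, base$lc_i)
})

test_that("degenerate inputs are rejected with informative errors", {
  img <- image_volume(array(1, c(4, 4, 2)), c(1, 1, 1))
  expect_error(select_brightest_connected(img, matrix(0L, 0, 3), k = 3),
               "empty")
  bad <- img
  bad$data[1, 1, 1] <- NA
  expect_error(select_brightest_connected(bad,
    as.matrix(expand.grid(1:2, 1:2, 1L)), k = 2), "finite")
  d <- small_lc_design(seed = 1)
  s <- generate_lc_phantom(d, 1)
  neg <- s
  neg$tse_image$data <- neg$tse_image$data - 1e6
  expect_error(measure_lc(neg), "reference mean")
})

test_that("a cluster larger than its box is refused, naming the box", {
  expect_error(generate_lc_phantom(small_lc_design(cluster = 5000L), 1),
               "lc_left")
})

test_that("a side with fewer than k reachable voxels is flagged, not fatal", {
  # 2x2x1 private boxes hold only 4 voxels; with k = 10 both sides come
  # back short and the averaged LC-I is NA while reference stays valid
  arr <- array(1, c(10, 10, 2))
  img <- image_volume(arr, c(1, 1, 1))
  boxes <- lcnbm:::.new_box_set(
    list(reference = as.matrix(expand.grid(1:10, 8:10, 1:2)),
         lc_left = as.matrix(expand.grid(1:2, 1:2, 1L)),
         lc_right = as.matrix(expand.grid(8:9, 1:2, 1L))),
    c(10L, 10L, 2L), c(1, 1, 1), "native",
    c(reference = 60, lc_left = 4, lc_right = 4))
  res <- compute_lc_intensity(img, boxes, k = 10)
  expect_false(res$qc$left$size_ok)
  expect_true(is.na(res$lc_i))
  expect_equal(res$lc_i_left, 1.0)
})
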