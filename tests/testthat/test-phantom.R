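test_that("identical design and seed reproduce bit-identical phantoms", {
  d <- small_lc_design(noise_sigma = 2, seed = 13)
  s1 <- generate_lc_phantom(d, 1)
  s2 <- generate_lc_phantom(d, 1)
  expect_identical(s1$tse_image$data, s2$tse_image$data)
  expect_identical(s1$true_lc_voxels, s2$true_lc_voxels)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$cohort, c2$cohort)
})

test_that("bright clusters sit inside their boxes and distractors outside all boxes", {
  d <- small_lc_design(noise_sigma = 0, seed = 17, distractors = 3L)
  s <- generate_lc_phantom(d, 1)
  dims <- dim(s$tse_image$data)
  box_lins <- lapply(s$native_boxes$boxes, lin_of, dims = dims)
  for (side in c("left", "right"))
    expect_true(all(lin_of(s$true_lc_voxels[[side]], dims) %in%
                      box_lins[[paste0("lc_", side)]]))
  # distractor intensity appears somewhere, but never inside a box
  bright <- which(s$tse_image$data ==
                    d$background * d$distractor_contrast)
  expect_gt(length(bright), 0)
  expect_length(intersect(bright, unlist(box_lins)), 0)
})

test_that("extraction agrees with extraction-on-truth across noisy subjects", {
  # oracle value: same seeds, selection replaced by the true voxel set
  n <- 100
  d <- small_lc_design(n_per_group = c(Control = n), noise_sigma = 2,
                       cluster = 10L, lc_contrast_by_group = 1.25,
                       seed = 29)
  diff <- vapply(seq_len(n), function(i) {
    s <- generate_lc_phantom(d, i)
    dims <- dim(s$tse_image$data)
    res <- measure_lc(s)
    truth_mean <- function(side) {
      lin <- (s$true_lc_voxels[[side]][, 3] - 1) * dims[1] * dims[2] +
        (s$true_lc_voxels[[side]][, 2] - 1) * dims[1] +
        s$true_lc_voxels[[side]][, 1]
      mean(s$tse_image$data[lin])
    }
    oracle <- (truth_mean("left") + truth_mean("right")) / 2 /
      res$reference_mean
    res$lc_i - oracle
  }, numeric(1))
  se <- stats::sd(diff) / sqrt(n)
  expect_lt(abs(mean(diff)), 3 * max(se, 1e-6))
})

test_that("cohort partial correlations converge to their designed targets", {
  d <- phantom_design(n_per_group = c(Control = 1250, AD = 1250,
                                      LATE = 1250, FTD = 1250),
                      lc_missing_by_group = 0, seed = 31)
  co <- generate_cohort(d)$cohort
  pc <- partial_correlation(co, "nbm_vol_norm", "hippocampus",
                            c("group", "age", "sex"))
  se <- 1 / sqrt(pc$n - pc$q - 3)
  expect_lt(abs(pc$r - 0.7), 3 * se)
  pc2 <- partial_correlation(co, "hippocampus", "entorhinal",
                             c("group", "age", "sex"))
  expect_lt(abs(pc2$r - 0.6), 3 * se)
})

test_that("designed LC-I missingness and cohort layout are honoured", {
  d <- phantom_design(seed = 3)   # study defaults: 15/23/17/17, 0/0/1/5
  co <- generate_cohort(d)$cohort
  expect_identical(nrow(co), 72L)
  miss <- tapply(is.na(co$lc_i), co$group, sum)
  expect_identical(as.integer(miss[c("Control", "AD", "LATE", "FTD")]),
                   c(0L, 0L, 1L, 5L))
  expect_true(all(table(co$group) == c(15, 23, 17, 17)))
})

test_that("invalid designs are rejected at construction", {
  expect_error(phantom_design(lc_contrast_by_group = c(-1, 1, 1, 1)),
               "> 0")
  expect_error(phantom_design(nbm_scale_by_group = 0), "> 0")
  expect_error(phantom_design(n_per_group = 0), ">= 1")
  bad_targets <- data.frame(x = c("lc_i", "lc_i", "nbm_vol_norm"),
                            y = c("nbm_vol_norm", "hippocampus",
                                  "hippocampus"),
                            r = c(0.9, 0.9, -0.9))
  expect_error(phantom_design(partial_corr_targets = bad_targets),
               "positive definite")
})

test_that("zero-displacement unit-scale NBM phantoms reproduce the template", {
  d <- phantom_design(n_per_group = c(Control = 1),
                      nbm_scale_by_group = 1, nbm_scale_sd = 0,
                      nbm_sinusoid_amplitude = 0,
                      lc_missing_by_group = 0, seed = 41)
  tpl <- synthetic_nbm_template()
  s <- generate_nbm_phantom(d, 1, template_mask = tpl, icv_mm3 = 1.4e6)
  both <- s$native_nbm_left$data + s$native_nbm_right$data
  expect_identical(both, tpl$data)
  expect_equal(s$true_nbm_volume_mm3, sum(tpl$data) / 2)
})
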