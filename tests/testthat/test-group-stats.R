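test_that("partial correlation with no covariates is plain Pearson", {
  set.seed(1)
  tab <- data.frame(x = rnorm(40), y = rnorm(40))
  pc <- partial_correlation(tab, "x", "y")
  expect_equal(pc$r, stats::cor(tab$x, tab$y), tolerance = 1e-12)
  ct <- stats::cor.test(tab$x, tab$y)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
})

test_that("partial correlation matches the inverse-correlation-matrix route", {
  # independent oracle: for continuous covariates, the partial correlation
  # is -P_xy / sqrt(P_xx P_yy) with P the precision of cor(x, y, Z)
  set.seed(2)
  n <- 300
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.6 * z1 - 0.3 * z2 + rnorm(n)
  y <- -0.4 * z1 + 0.5 * z2 + rnorm(n)
  tab <- data.frame(x = x, y = y, z1 = z1, z2 = z2)
  pc <- partial_correlation(tab, "x", "y", c("z1", "z2"))
  P <- solve(stats::cor(cbind(x, y, z1, z2)))
  expect_equal(pc$r, -P[1, 2] / sqrt(P[1, 1] * P[2, 2]),
               tolerance = 1e-10)
})

test_that("generated partial correlation is recovered within 3 Fisher-z SE", {
  set.seed(3)
  n <- 5000
  z <- rnorm(n)
  # construct x, y with partial correlation 0.5 given z
  e <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, 0.5, 0.5, 1), 2))
  tab <- data.frame(x = 0.8 * z + e[, 1], y = -0.5 * z + e[, 2], z = z)
  pc <- partial_correlation(tab, "x", "y", "z")
  expect_lt(abs(pc$r - 0.5), 3 / sqrt(n - 1 - 3))
})

test_that("confounded variables decorrelate after adjustment", {
  set.seed(4)
  n <- 2000
  z <- rnorm(n)
  tab <- data.frame(x = z + rnorm(n), y = z + rnorm(n), z = z)
  plain <- stats::cor(tab$x, tab$y)
  pc <- partial_correlation(tab, "x", "y", "z")
  expect_gt(plain, 0.3)
  expect_lt(abs(pc$r), 3 / sqrt(n - 1 - 3))
})

test_that("partial correlation is invariant under affine rescaling", {
  set.seed(5)
  tab <- data.frame(x = rnorm(60), y = rnorm(60), age = rnorm(60, 70, 5),
                    sex = factor(sample(c("F", "M"), 60, TRUE)))
  base <- partial_correlation(tab, "x", "y", c("age", "sex"))
  tab2 <- within(tab, { x <- 3 * x - 7; y <- 0.2 * y + 40
                        age <- (age - 70) / 5 })
  resc <- partial_correlation(tab2, "x", "y", c("age", "sex"))
  expect_equal(resc$r, base$r, tolerance = 1e-10)
  expect_equal(resc$p, base$p, tolerance = 1e-10)
})

test_that("degenerate partial correlations are errors", {
  tab <- data.frame(x = rnorm(10), z = rnorm(10))
  tab$y <- 2 * tab$z          # fully explained by the covariate
  expect_error(partial_correlation(tab, "x", "y", "z"),
               "zero residual variance")
  tiny <- data.frame(x = rnorm(3), y = rnorm(3), z = rnorm(3))
  expect_error(partial_correlation(tiny, "x", "y", "z"),
               "complete cases")
  expect_error(partial_correlation(tab, "x", "nope"), "not in cohort")
})

test_that("balanced covariates leave the adjusted difference equal to the raw one", {
  ages <- c(62, 65, 68, 71, 74, 77)
  sexes <- c("F", "F", "F", "M", "M", "M")
  set.seed(6)
  tab <- data.frame(group = factor(rep(c("Control", "AD"), each = 6)),
                    age = c(ages, ages), sex = factor(c(sexes, sexes)),
                    y = rnorm(12))
  res <- ancova_compare(tab, "y", c("Control", "AD"))
  raw <- mean(tab$y[tab$group == "AD"]) -
    mean(tab$y[tab$group == "Control"])
  expect_equal(res$diff, raw, tolerance = 1e-10)
})

test_that("the reported F is the group-term F of the nested-model comparison", {
  set.seed(7)
  tab <- data.frame(group = factor(rep(c("a", "b"), each = 15)),
                    age = rnorm(30, 70, 6),
                    sex = factor(sample(c("F", "M"), 30, TRUE)),
                    y = rnorm(30))
  res <- ancova_compare(tab, "y", c("a", "b"))
  f0 <- stats::lm(y ~ age + sex, tab)
  f1 <- stats::lm(y ~ group + age + sex, tab)
  Ftab <- stats::anova(f0, f1)
  expect_equal(res$F, Ftab$F[2], tolerance = 1e-10)
  expect_equal(res$p, Ftab$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("collinear or under-filled designs are refused", {
  tab <- data.frame(group = factor(rep(c("a", "b"), each = 6)),
                    age = rnorm(12, 70, 5),
                    sex = factor(rep(c("M", "F"), c(6, 6))),
                    y = rnorm(12))
  # sex is constant within each group: confounded with the group term
  expect_error(ancova_compare(tab, "y", c("a", "b")), "collinear")
  tiny <- tab[c(1:2, 7:12), ]
  expect_error(ancova_compare(tiny, "y", c("a", "b")), "fewer than 3")
  expect_error(ancova_compare(tab, "nope", c("a", "b")), "not in cohort")
})

test_that("Bonferroni adjustment multiplies, caps and validates", {
  expect_equal(bonferroni_adjust(0.001, 48), 0.048)
  expect_equal(bonferroni_adjust(0.5, 6), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 2), c(0.4, 0.08))
  expect_identical(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(1.2, 4), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(rep(0.01, 5), 4), "smaller")
})

test_that("the default plan reproduces the declared family sizes", {
  plan <- default_analysis_plan()
  sizes <- lcnbm:::.family_sizes(plan)
  expect_identical(unname(sizes[c("lc_nbm_group", "imaging_group",
                                  "cognitive_group", "imaging_corr")]),
                   c(6L, 48L, 30L, 64L))
  expect_identical(unname(sizes["cognitive_corr"]), 48L)
  # restricting the plan to one control/patient pair: 8 imaging tests
  plan2 <- default_analysis_plan(groups = c("Control", "AD"))
  expect_identical(unname(lcnbm:::.family_sizes(plan2)["imaging_group"]),
                   8L)
})

test_that("running the plan yields a manifest, summaries and an r2 matrix", {
  d <- phantom_design(seed = 51)
  co <- generate_cohort(d)$cohort
  res <- run_analysis_plan(co)
  expect_identical(res$manifest$declared_size, c(6L, 48L, 30L, 48L, 64L))
  expect_identical(res$manifest$tests_computed,
                   c(6L, 48L, 30L, 40L, 64L))
  expect_true(all(res$ancova$p_adj >= res$ancova$p, na.rm = TRUE))
  expect_true(all(res$ancova$p_adj <= 1))
  expect_true(all(abs(res$correlations$r) <= 1))
  expect_identical(dim(res$r2_matrix), c(8L, 13L))
  expect_false(anyNA(res$r2_matrix))
  # group summary covers every measure x group cell
  expect_identical(nrow(res$group_summary), 15L * 4L)
  expect_error(run_analysis_plan(co[, setdiff(names(co), "mmse")]),
               "mmse")
})

test_that("a null cohort stays quiet after Bonferroni in the correlation family", {
  d <- phantom_design(
    lc_contrast_by_group = 1.2, nbm_scale_by_group = 1,
    measure_model = list(means = matrix(
      rep(c(1.2, 0.25, 2.45, 0.96, 1.28, 2.86, 2.78, 2.33, 2.31, 2.57,
            28.8, 141, 80.7, 185.6, 61.6), each = 4), 4,
      dimnames = list(c("Control", "AD", "LATE", "FTD"),
                      lcnbm:::.lcnbm_measure_names()))),
    partial_corr_targets = data.frame(x = character(0),
                                      y = character(0), r = numeric(0)),
    lc_missing_by_group = 0, seed = 61)
  co <- generate_cohort(d)$cohort
  res <- run_analysis_plan(co)
  imaging <- res$correlations[res$correlations$family == "imaging_corr", ]
  expect_lt(mean(imaging$p_adj < 0.05), 0.05)
})
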