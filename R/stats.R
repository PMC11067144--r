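#' ANCOVA comparison of one measure between two groups
#'
#' Fits the linear model \code{measure ~ group + covariates} on the
#' complete cases of the two requested groups and reports the test of the
#' group term: the adjusted mean difference (second group minus first),
#' its t statistic, the equivalent single-df F (\code{t^2}) and the raw
#' two-sided p-value. Missing cells are handled by listwise deletion and
#' the complete-case n is always reported.
#'
#' @param table cohort data frame (one row per subject).
#' @param measure name of the measure column.
#' @param groups length-2 character vector: the contrast is
#'   \code{groups[2]} minus \code{groups[1]}.
#' @param covariates covariate column names (default age and sex).
#' @return an object of class \code{ancova_result} (also a one-row data
#'   frame) with columns \code{measure}, \code{contrast}, \code{diff},
#'   \code{t}, \code{F}, \code{p}, \code{n}.
#' @export
ancova_compare <- function(table, measure, groups,
                           covariates = c("age", "sex")) {
  stopifnot(length(groups) == 2L)
  missing_cols <- setdiff(c(measure, "group", covariates), names(table))
  if (length(missing_cols))
    stop("column(s) not in cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- table[table$group %in% groups, c(measure, "group", covariates),
               drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  sub$group <- factor(as.character(sub$group), levels = groups)
  counts <- table(sub$group)
  if (any(counts < 3L))
    stop("fewer than 3 complete cases in group ",
         names(counts)[which.min(counts)], call. = FALSE)
  for (cv in covariates) {
    v <- sub[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("covariate `", cv, "` is constant on the analysis subset",
           call. = FALSE)
  }
  form <- stats::reformulate(c("group", covariates), response = measure)
  fit <- stats::lm(form, data = sub)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: collinearity between group and covariate(s) ",
         paste(covariates, collapse = ", "),
         " (e.g. a covariate constant within a group)", call. = FALSE)
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))[1L]
  res <- data.frame(measure = measure,
                    contrast = paste(groups[2L], "vs", groups[1L]),
                    diff = sm[row, "Estimate"],
                    t = sm[row, "t value"],
                    F = sm[row, "t value"]^2,
                    p = sm[row, "Pr(>|t|)"],
                    n = nrow(sub), stringsAsFactors = FALSE)
  class(res) <- c("ancova_result", "data.frame")
  res
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes \code{x} and \code{y} on an intercept plus the covariate
#' columns by least squares and returns the Pearson correlation of the
#' residuals. Categorical covariates (including \code{group}) are
#' dummy-coded through \code{model.matrix}, so "corrected for diagnostic
#' group" means partialling out the group indicator columns. The p-value
#' comes from \code{t = r * sqrt(df / (1 - r^2))} with
#' \code{df = n - 2 - q}, q the number of covariate columns after
#' dummy coding.
#'
#' @param table cohort data frame.
#' @param x,y names of the two measure columns.
#' @param covariates covariate column names (may be empty, giving the
#'   plain Pearson correlation).
#' @return an object of class \code{partial_corr_result} (also a one-row
#'   data frame) with columns \code{x}, \code{y}, \code{covariates},
#'   \code{n}, \code{q}, \code{r}, \code{r2}, \code{df}, \code{p}.
#' @export
partial_correlation <- function(table, x, y, covariates = character(0)) {
  missing_cols <- setdiff(c(x, y, covariates), names(table))
  if (length(missing_cols))
    stop("column(s) not in cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- table[, c(x, y, covariates), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  n <- nrow(sub)
  if (length(covariates)) {
    X <- stats::model.matrix(stats::reformulate(covariates), data = sub)
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  } else {
    X <- matrix(1, n, 1L)
  }
  q <- ncol(X) - 1L
  if (n - 2L - q < 1L)
    stop("not enough complete cases (n = ", n, ") for ", q,
         " covariate column(s)", call. = FALSE)
  res <- stats::lm.fit(X, cbind(sub[[x]], sub[[y]]))$residuals
  if (any(apply(res, 2L, stats::sd) < 1e-12))
    stop("zero residual variance: `", x, "` or `", y,
         "` is fully explained by the covariates", call. = FALSE)
  r <- stats::cor(res[, 1L], res[, 2L])
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  out <- data.frame(x = x, y = y,
                    covariates = paste(covariates, collapse = "+"),
                    n = n, q = q, r = r, r2 = r^2, df = df,
                    p = 2 * stats::pt(-abs(tval), df),
                    stringsAsFactors = FALSE)
  class(out) <- c("partial_corr_result", "data.frame")
  out
}

#' Bonferroni adjustment over a declared family
#'
#' Multiplies raw p-values by the declared family size and caps at 1. The
#' family may be declared larger than the number of p-values actually
#' computed (e.g. when some tests in the family are not run).
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param family_size declared number of tests in the family.
#' @return adjusted p-values, \code{pmin(1, p * family_size)}.
#' @export
bonferroni_adjust <- function(p, family_size) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (family_size < sum(!is.na(p)))
    stop("`family_size` (", family_size, ") is smaller than the number ",
         "of p-values in the family (", sum(!is.na(p)), ")",
         call. = FALSE)
  pmin(1, p * family_size)
}

#' Default analysis plan
#'
#' Encodes the study's test families over a four-group cohort with
#' Control as reference:
#' \itemize{
#'   \item \code{lc_nbm_group}: LC-I and NBM volume vs controls for each
#'     patient group — 2 x 3 = 6 ANCOVA tests;
#'   \item \code{imaging_group}: 8 other imaging measures (3
#'     medial-temporal volumes + 5 VOI thicknesses) over all 6 pairwise
#'     group contrasts — 48 tests;
#'   \item \code{cognitive_group}: 5 cognitive scores over all 6 pairwise
#'     contrasts — 30 tests;
#'   \item \code{imaging_corr}: partial correlations of LC-I and NBM
#'     volume with the 8 imaging measures in 4 analysis sets (all
#'     patients with group dummies, and each patient group) — 64 tests;
#'   \item \code{cognitive_corr}: the same predictors against the 5
#'     cognitive scores in the 4 sets — 40 computed tests inside a
#'     declared family of \code{cognitive_family_size} (default 48).
#' }
#' Imaging correlations are adjusted for age and sex (plus group in the
#' pooled set); cognitive correlations for age (plus group in the pooled
#' set).
#'
#' @param groups group labels in order; the first is the control group.
#' @param key_measures the two primary measures.
#' @param imaging_measures the 8 secondary imaging measures.
#' @param cognitive_measures the 5 cognitive scores.
#' @param cognitive_family_size declared size of the cognitive
#'   correlation family.
#' @return a list of class \code{analysis_plan}.
#' @export
default_analysis_plan <- function(groups = c("Control", "AD", "LATE",
                                             "FTD"),
                                  key_measures = c("lc_i",
                                                   "nbm_vol_norm"),
                                  imaging_measures = c(
                                    "hippocampus", "amygdala",
                                    "entorhinal", "ct_temporal_meta",
                                    "ct_lateral_temporal",
                                    "ct_lateral_parietal",
                                    "ct_medial_parietal", "ct_frontal"),
                                  cognitive_measures = c(
                                    "mmse", "mattis", "memory",
                                    "parietal", "executive"),
                                  cognitive_family_size = 48L) {
  control <- groups[1L]
  patients <- groups[-1L]
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  vs_control <- lapply(patients, function(g) c(control, g))
  structure(list(groups = groups, control = control,
                 key_measures = key_measures,
                 imaging_measures = imaging_measures,
                 cognitive_measures = cognitive_measures,
                 contrasts_vs_control = vs_control,
                 contrasts_all_pairs = pairs,
                 ancova_covariates = c("age", "sex"),
                 cognitive_family_size = as.integer(cognitive_family_size)),
            class = "analysis_plan")
}

.family_sizes <- function(plan) {
  c(lc_nbm_group = length(plan$key_measures) *
      length(plan$contrasts_vs_control),
    imaging_group = length(plan$imaging_measures) *
      length(plan$contrasts_all_pairs),
    cognitive_group = length(plan$cognitive_measures) *
      length(plan$contrasts_all_pairs),
    cognitive_corr = plan$cognitive_family_size,
    imaging_corr = length(plan$key_measures) *
      length(plan$imaging_measures) * (1L + length(plan$groups) - 1L))
}

#' Run the full analysis plan on a cohort table
#'
#' Executes every family of the plan with listwise deletion per test,
#' applies the Bonferroni correction within each declared family, and
#' assembles a group-comparison table (one row per measure and contrast)
#' and a squared-partial-correlation matrix (analysis sets and predictors
#' in rows, target measures in columns), plus a machine-readable family
#' manifest.
#'
#' @param table cohort data frame (as from \code{\link{generate_cohort}}
#'   or the imaging pipeline).
#' @param plan an \code{analysis_plan}.
#' @param alpha significance level used for the summary flags.
#' @return a list of class \code{lcnbm_results} with elements
#'   \code{group_summary}, \code{ancova}, \code{correlations},
#'   \code{r2_matrix} and \code{manifest}.
#' @export
run_analysis_plan <- function(table, plan = default_analysis_plan(),
                              alpha = 0.05) {
  stopifnot(inherits(plan, "analysis_plan"))
  all_measures <- c(plan$key_measures, plan$imaging_measures,
                    plan$cognitive_measures)
  missing_cols <- setdiff(c(all_measures, "group", "age", "sex"),
                          names(table))
  if (length(missing_cols))
    stop("analysis plan references missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  sizes <- .family_sizes(plan)
  run_family <- function(measures, contrasts, family) {
    rows <- lapply(measures, function(m)
      lapply(contrasts, function(gp)
        ancova_compare(table, m, gp, plan$ancova_covariates)))
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    out$family <- family
    out$family_size <- sizes[[family]]
    out$p_adj <- bonferroni_adjust(out$p, sizes[[family]])
    out
  }
  anc <- rbind(
    run_family(plan$key_measures, plan$contrasts_vs_control,
               "lc_nbm_group"),
    run_family(plan$imaging_measures, plan$contrasts_all_pairs,
               "imaging_group"),
    run_family(plan$cognitive_measures, plan$contrasts_all_pairs,
               "cognitive_group"))

  patients <- table[table$group %in% plan$groups[-1L], , drop = FALSE]
  patients$group <- droplevels(factor(patients$group))
  sets <- c(list(all_patients = patients),
            stats::setNames(lapply(plan$groups[-1L], function(g)
              table[table$group == g, , drop = FALSE]), plan$groups[-1L]))
  corr_one <- function(set_name, data, x, y, imaging) {
    covs <- if (imaging) c("age", "sex") else "age"
    if (set_name == "all_patients") covs <- c("group", covs)
    res <- partial_correlation(data, x, y, covs)
    res$set <- set_name
    res
  }
  corr_family <- function(targets, family, imaging) {
    rows <- list()
    for (s in names(sets)) for (x in plan$key_measures)
      for (y in targets)
        rows[[length(rows) + 1L]] <- corr_one(s, sets[[s]], x, y, imaging)
    out <- do.call(rbind, rows)
    out$family <- family
    out$family_size <- sizes[[family]]
    out$p_adj <- bonferroni_adjust(out$p, sizes[[family]])
    out
  }
  corr <- rbind(corr_family(plan$imaging_measures, "imaging_corr", TRUE),
                corr_family(plan$cognitive_measures, "cognitive_corr",
                            FALSE))

  # Table-1-style summary: group means (SD) with significance flags
  grp_stats <- do.call(rbind, lapply(all_measures, function(m) {
    do.call(rbind, lapply(plan$groups, function(g) {
      v <- table[[m]][table$group == g]
      data.frame(measure = m, group = g, mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  flag <- function(m, g) {
    vs_ctrl <- anc$measure == m & anc$contrast ==
      paste(g, "vs", plan$control)
    sig_ctrl <- any(anc$p_adj[vs_ctrl] < alpha)
    others <- setdiff(plan$groups, c(g, plan$control))
    vs_oth <- anc$measure == m &
      (anc$contrast %in% c(paste(g, "vs", others),
                           paste(others, "vs", g)))
    sig_oth <- length(which(vs_oth)) > 0 && all(anc$p_adj[vs_oth] < alpha)
    if (sig_oth && sig_ctrl) "#" else if (sig_ctrl) "*" else ""
  }
  grp_stats$flag <- mapply(flag, grp_stats$measure, grp_stats$group)

  # Table-2-style r^2 matrix: rows = set x predictor, cols = targets
  targets_all <- c(plan$cognitive_measures, plan$imaging_measures)
  r2 <- matrix(NA_real_, length(sets) * length(plan$key_measures),
               length(targets_all),
               dimnames = list(NULL, targets_all))
  rn <- character(nrow(r2))
  i <- 0L
  for (s in names(sets)) for (x in plan$key_measures) {
    i <- i + 1L
    rn[i] <- paste(s, x, sep = ".")
    for (y in targets_all) {
      hit <- corr$set == s & corr$x == x & corr$y == y
      if (any(hit)) r2[i, y] <- corr$r2[hit][1L]
    }
  }
  rownames(r2) <- rn

  manifest <- data.frame(family = names(sizes),
                         declared_size = unname(sizes),
                         tests_computed = c(
                           sum(anc$family == "lc_nbm_group"),
                           sum(anc$family == "imaging_group"),
                           sum(anc$family == "cognitive_group"),
                           sum(corr$family == "cognitive_corr"),
                           sum(corr$family == "imaging_corr")),
                         stringsAsFactors = FALSE)
  structure(list(group_summary = grp_stats, ancova = anc,
                 correlations = corr, r2_matrix = r2,
                 manifest = manifest, alpha = alpha),
            class = "lcnbm_results")
}

#' @export
print.lcnbm_results <- function(x, ...) {
  cat("<lcnbm_results>\n  families:\n")
  print(x$manifest, row.names = FALSE)
  cat("  ", sum(x$ancova$p_adj < x$alpha),
      "group contrasts significant after Bonferroni;",
      sum(x$correlations$p_adj < x$alpha),
      "partial correlations significant\n")
  invisible(x)
}
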