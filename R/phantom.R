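#' Phantom study design
#'
#' Describes a synthetic cohort with known ground truth: per-group sample
#' sizes, the target LC-to-reference intensity ratio and the NBM mask
#' scale factor per group, the noise model of the turbo-spin-echo slab,
#' acquisition grids, covariate distributions and the partial-correlation
#' structure of the generated measures. The defaults emulate the study
#' conditions of a four-group memory-clinic cohort: groups
#' Control/AD/LATE/FTD with n = 15/23/17/17, TSE voxels 0.4 x 0.4 x 3 mm,
#' 3D-T1 voxels 1 x 1 x 1 mm, group ages and cognitive scores on the
#' scales of a standard dementia battery, and LC-I missingness in 1 LATE
#' and 5 FTD subjects.
#'
#' @param n_per_group named integer vector of per-group sample sizes.
#' @param group_labels ordered group labels (default from
#'   \code{names(n_per_group)}).
#' @param lc_contrast_by_group target LC/reference intensity ratio per
#'   group (dimensionless, > 0).
#' @param nbm_scale_by_group linear scale factor applied to the template
#'   NBM mask per group (> 0; volume scales with its cube).
#' @param noise_sigma additive noise SD of the TSE slab, in intensity
#'   units (the default background is 100, so 2 means 2\% of background).
#' @param background TSE background intensity.
#' @param noise_model \code{"gaussian"} (default) or \code{"rician"}.
#' @param tse_voxel,tse_grid LC-slab voxel size (mm) and grid.
#' @param t1_voxel 3D-T1 voxel size (mm).
#' @param lc_cluster_voxels voxels per bright LC cluster (>= the selection
#'   size).
#' @param distractors number of bright distractor blobs placed outside all
#'   boxes.
#' @param distractor_contrast intensity ratio of distractors.
#' @param box_geometry geometry overrides passed to
#'   \code{\link{build_template_boxes}}.
#' @param nbm_scale_sd log-scale between-subject SD of the NBM scale.
#' @param nbm_sinusoid_amplitude,nbm_sinusoid_wavelength parameters (mm)
#'   of the smooth displacement composed with the per-group scaling.
#' @param covariate_model list overriding the age/sex/ICV model
#'   (\code{age_mean}, \code{age_sd}, \code{male_frac} per group;
#'   \code{icv_male}, \code{icv_female}, \code{icv_sd}).
#' @param measure_model list overriding generated measure means, SDs and
#'   age slopes.
#' @param partial_corr_targets data frame with columns \code{x}, \code{y},
#'   \code{r}: target partial correlations (given group, age, sex) between
#'   generated measures. The implied residual correlation matrix must be
#'   positive definite.
#' @param lc_missing_by_group named integer vector: number of subjects per
#'   group whose LC-I is set missing (emulating technical failures).
#' @param seed integer RNG seed; identical design + seed reproduce
#'   bit-identical phantoms.
#' @return an object of class \code{phantom_design}.
#' @export
phantom_design <- function(n_per_group = c(Control = 15, AD = 23,
                                           LATE = 17, FTD = 17),
                           group_labels = NULL,
                           lc_contrast_by_group = NULL,
                           nbm_scale_by_group = NULL,
                           noise_sigma = 2, background = 100,
                           noise_model = c("gaussian", "rician"),
                           tse_voxel = c(0.4, 0.4, 3),
                           tse_grid = c(256, 256, 20),
                           t1_voxel = c(1, 1, 1),
                           lc_cluster_voxels = 20L,
                           distractors = 2L, distractor_contrast = 1.6,
                           box_geometry = list(),
                           nbm_scale_sd = 0.03,
                           nbm_sinusoid_amplitude = 0.3,
                           nbm_sinusoid_wavelength = 16,
                           covariate_model = list(),
                           measure_model = list(),
                           partial_corr_targets = NULL,
                           lc_missing_by_group = NULL,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(group_labels))
    group_labels <- if (!is.null(names(n_per_group))) names(n_per_group)
      else c("Control", "AD", "LATE", "FTD")[seq_along(n_per_group)]
  n_per_group <- as.integer(rep_len(n_per_group, length(group_labels)))
  names(n_per_group) <- group_labels
  if (any(n_per_group < 1L))
    stop("`n_per_group` must be >= 1 for every group", call. = FALSE)

  fill_by_group <- function(x, defaults, fallback) {
    if (is.null(x)) {
      out <- defaults[group_labels]
      out[is.na(out)] <- fallback
    } else {
      out <- rep_len(as.numeric(x), length(group_labels))
    }
    names(out) <- group_labels
    out
  }
  lc_contrast_by_group <- fill_by_group(
    lc_contrast_by_group,
    c(Control = 1.30, AD = 1.18, LATE = 1.18, FTD = 1.22), 1.30)
  nbm_scale_by_group <- fill_by_group(
    nbm_scale_by_group,
    c(Control = 1.00, AD = 0.85, LATE = 0.85, FTD = 0.87), 1.00)
  user_missing <- !is.null(lc_missing_by_group)
  lc_missing_by_group <- fill_by_group(
    lc_missing_by_group,
    c(Control = 0, AD = 0, LATE = 1, FTD = 5), 0)
  # default missingness is capped by group size so small cohorts stay valid
  if (!user_missing)
    lc_missing_by_group <- pmin(lc_missing_by_group, n_per_group)
  if (any(lc_contrast_by_group <= 0))
    stop("all LC contrast ratios must be > 0", call. = FALSE)
  if (any(nbm_scale_by_group <= 0))
    stop("all NBM scale factors must be > 0", call. = FALSE)
  if (any(lc_missing_by_group > n_per_group))
    stop("more missing LC-I values requested than subjects in a group",
         call. = FALSE)
  if (noise_sigma < 0 || background <= 0)
    stop("`noise_sigma` must be >= 0 and `background` > 0", call. = FALSE)
  if (lc_cluster_voxels < 1L)
    stop("`lc_cluster_voxels` must be >= 1", call. = FALSE)

  cov_model <- utils::modifyList(list(
    age_mean = c(Control = 68.7, AD = 70.4, LATE = 77.3, FTD = 70.1),
    age_sd = c(Control = 3.6, AD = 6.5, LATE = 5.2, FTD = 8.6),
    male_frac = c(Control = 5 / 15, AD = 12 / 23, LATE = 11 / 17,
                  FTD = 9 / 17),
    icv_male = 1.55e6, icv_female = 1.35e6, icv_sd = 8e4,
    age_ref = 70), covariate_model)
  for (f in c("age_mean", "age_sd", "male_frac")) {
    v <- cov_model[[f]][group_labels]
    v[is.na(v)] <- switch(f, age_mean = 70, age_sd = 6, male_frac = 0.5)
    names(v) <- group_labels
    cov_model[[f]] <- v
  }

  meas_model <- .default_measure_model(group_labels, lc_contrast_by_group,
                                       nbm_scale_by_group)
  meas_model <- utils::modifyList(meas_model, measure_model)
  if (is.null(partial_corr_targets))
    partial_corr_targets <- .default_partial_corr_targets()
  R <- .residual_correlation(colnames(meas_model$means),
                             partial_corr_targets)

  design <- structure(list(
    n_per_group = n_per_group, group_labels = group_labels,
    lc_contrast_by_group = lc_contrast_by_group,
    nbm_scale_by_group = nbm_scale_by_group,
    noise_sigma = noise_sigma, background = background,
    noise_model = noise_model,
    tse_voxel = .check_positive_triple(tse_voxel, "tse_voxel"),
    tse_grid = as.integer(tse_grid),
    t1_voxel = .check_positive_triple(t1_voxel, "t1_voxel"),
    lc_cluster_voxels = as.integer(lc_cluster_voxels),
    distractors = as.integer(distractors),
    distractor_contrast = distractor_contrast,
    box_geometry = box_geometry,
    nbm_scale_sd = nbm_scale_sd,
    nbm_sinusoid_amplitude = nbm_sinusoid_amplitude,
    nbm_sinusoid_wavelength = nbm_sinusoid_wavelength,
    covariate_model = cov_model, measure_model = meas_model,
    partial_corr_targets = partial_corr_targets,
    residual_correlation = R,
    lc_missing_by_group = lc_missing_by_group,
    seed = as.integer(seed)), class = "phantom_design")
  design
}

#' @export
print.phantom_design <- function(x, ...) {
  cat("<phantom_design> groups:",
      paste(sprintf("%s (n=%d)", x$group_labels, x$n_per_group),
            collapse = ", "), "\n  LC contrast:",
      paste(signif(x$lc_contrast_by_group, 3), collapse = "/"),
      " NBM scale:", paste(signif(x$nbm_scale_by_group, 3),
                           collapse = "/"),
      " noise:", x$noise_model, x$noise_sigma, " seed:", x$seed, "\n")
  invisible(x)
}

# Generated measure vocabulary and group means/SDs/age slopes. Means of
# the non-LC/NBM measures follow the scales of a standard dementia
# battery and FreeSurfer-style normalized volumes; unknown group labels
# fall back to the Control row (null group differences).
.lcnbm_measure_names <- function() {
  c("lc_i", "nbm_vol_norm", "hippocampus", "amygdala", "entorhinal",
    "ct_temporal_meta", "ct_lateral_temporal", "ct_lateral_parietal",
    "ct_medial_parietal", "ct_frontal",
    "mmse", "mattis", "memory", "parietal", "executive")
}

.default_measure_model <- function(labels, lc_contrast, nbm_scale) {
  base <- rbind(
    Control = c(NA, NA, 2.45, 0.96, 1.28, 2.86, 2.78, 2.33, 2.31, 2.57,
                28.8, 141, 80.7, 185.6, 61.6),
    AD      = c(NA, NA, 1.92, 0.75, 0.93, 2.53, 2.50, 2.14, 2.13, 2.39,
                24.4, 126, 32.7, 180.0, 47.7),
    LATE    = c(NA, NA, 1.72, 0.72, 0.90, 2.55, 2.48, 2.15, 2.12, 2.32,
                24.6, 129, 38.1, 182.5, 48.2),
    FTD     = c(NA, NA, 1.77, 0.68, 0.85, 2.25, 2.29, 2.07, 1.99, 2.19,
                20.9, 110, 38.2, 149.6, 30.3))
  colnames(base) <- .lcnbm_measure_names()
  means <- base[match(labels, rownames(base)), , drop = FALSE]
  means[is.na(match(labels, rownames(base))), ] <- base["Control", ]
  rownames(means) <- labels
  means[, "lc_i"] <- lc_contrast[labels]
  means[, "nbm_vol_norm"] <- 0.25 * nbm_scale[labels]^3
  sds <- c(lc_i = 0.06, nbm_vol_norm = 0.03, hippocampus = 0.3125,
           amygdala = 0.1525, entorhinal = 0.2675,
           ct_temporal_meta = 0.21, ct_lateral_temporal = 0.18,
           ct_lateral_parietal = 0.155, ct_medial_parietal = 0.1475,
           ct_frontal = 0.1425, mmse = 3.025, mattis = 10.925,
           memory = 15.8, parietal = 10.375, executive = 10.575)
  slopes <- c(lc_i = -0.002, nbm_vol_norm = -0.001, hippocampus = -0.012,
              amygdala = -0.005, entorhinal = -0.008,
              ct_temporal_meta = -0.008, ct_lateral_temporal = -0.008,
              ct_lateral_parietal = -0.008, ct_medial_parietal = -0.008,
              ct_frontal = -0.008, mmse = -0.05, mattis = -0.2,
              memory = -0.2, parietal = -0.2, executive = -0.2)
  list(means = means, sds = sds, age_slopes = slopes)
}

.default_partial_corr_targets <- function() {
  data.frame(
    x = c("nbm_vol_norm", "nbm_vol_norm", "nbm_vol_norm", "hippocampus",
          "hippocampus", "amygdala", "lc_i", "hippocampus",
          "ct_temporal_meta"),
    y = c("hippocampus", "amygdala", "entorhinal", "amygdala",
          "entorhinal", "entorhinal", "nbm_vol_norm", "ct_temporal_meta",
          "ct_lateral_temporal"),
    r = c(0.7, 0.7, 0.6, 0.6, 0.6, 0.6, 0.3, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

# residual (conditional on covariates) correlation matrix from targets
.residual_correlation <- function(measures, targets) {
  R <- diag(length(measures))
  dimnames(R) <- list(measures, measures)
  for (i in seq_len(nrow(targets))) {
    x <- targets$x[i]; y <- targets$y[i]; r <- targets$r[i]
    if (!x %in% measures || !y %in% measures)
      stop("partial correlation target references unknown measure: ",
           x, " / ", y, call. = FALSE)
    if (abs(r) >= 1)
      stop("partial correlation targets must lie in (-1, 1)",
           call. = FALSE)
    R[x, y] <- r
    R[y, x] <- r
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("requested partial-correlation matrix is not positive definite ",
         "(min eigenvalue ", signif(ev, 3), ")", call. = FALSE)
  R
}

.group_of_subject <- function(design, subject_index) {
  groups <- rep(design$group_labels, design$n_per_group)
  if (subject_index < 1L || subject_index > length(groups))
    stop("`subject_index` out of range (cohort has ", length(groups),
         " subjects)", call. = FALSE)
  groups[subject_index]
}

# place n_blob-voxel bright distractor blobs outside every box
.place_distractors <- function(arr, boxes, design, dimg) {
  if (design$distractors < 1L) return(arr)
  excl <- array(FALSE, dimg)
  margin <- 3L
  for (b in boxes$boxes) {
    lo <- pmax(1L, apply(b, 2L, min) - margin)
    hi <- pmin(dimg, apply(b, 2L, max) + margin)
    excl[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  radius_vox <- pmax(1, round(1.2 / design$tse_voxel))
  placed <- 0L
  tries <- 0L
  while (placed < design$distractors && tries < 200L) {
    tries <- tries + 1L
    ctr <- c(sample.int(dimg[1L], 1L), sample.int(dimg[2L], 1L),
             sample.int(dimg[3L], 1L))
    lo <- pmax(1L, ctr - radius_vox)
    hi <- pmin(dimg, ctr + radius_vox)
    block <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    keep <- ((block$x - ctr[1]) / max(radius_vox[1], 1))^2 +
      ((block$y - ctr[2]) / max(radius_vox[2], 1))^2 +
      ((block$z - ctr[3]) / max(radius_vox[3], 1))^2 <= 1
    vox <- as.matrix(block[keep, , drop = FALSE])
    lin <- .linear_index(vox, dimg)
    if (any(excl[lin])) next
    arr[lin] <- design$background * design$distractor_contrast
    placed <- placed + 1L
  }
  arr
}

#' Generate an LC phantom subject
#'
#' Builds a turbo-spin-echo-like slab containing a uniform background, one
#' compact connected bright cluster centred inside each LC bounding box at
#' the group's target contrast ratio, optional bright distractor blobs
#' outside all boxes, and additive noise. The ground-truth cluster voxel
#' sets are recorded before noise is added. The subject's
#' template-to-native transform is a whole-voxel translation (centre
#' alignment plus a small per-subject jitter), so resampled box volumes
#' are preserved exactly.
#'
#' @param design a \code{phantom_design}.
#' @param subject_index subject position in the cohort (groups are laid
#'   out consecutively in label order).
#' @return a \code{phantom_subject} list with elements \code{subject_id},
#'   \code{group}, \code{tse_image}, \code{transform},
#'   \code{native_boxes}, \code{true_lc_voxels},
#'   \code{true_lc_contrast} and \code{template_boxes}.
#' @export
generate_lc_phantom <- function(design, subject_index) {
  stopifnot(inherits(design, "phantom_design"))
  group <- .group_of_subject(design, subject_index)
  set.seed(.subject_seed(design$seed, subject_index, stage = 1L))
  contrast <- design$lc_contrast_by_group[[group]]
  spacing <- design$tse_voxel
  dimg <- design$tse_grid
  tpl <- build_template_boxes(spacing, design$box_geometry)

  base_shift <- floor((dimg - tpl$grid_dim) / 2)
  jitter <- c(sample(-2:2, 2L, replace = TRUE), sample(-1:1, 1L))
  shift_vox <- base_shift + jitter
  transform <- deformation_translation(shift_vox * spacing)
  native_boxes_list <- lapply(tpl$boxes, function(b)
    sweep(b, 2L, as.integer(shift_vox), `+`))
  for (nm in names(native_boxes_list)) {
    b <- native_boxes_list[[nm]]
    if (any(b < 1L) || any(sweep(b, 2L, dimg, `>`)))
      stop("TSE grid too small: box `", nm,
           "` falls outside the native grid", call. = FALSE)
  }
  native_boxes <- .new_box_set(native_boxes_list, dimg, spacing, "native",
                               tpl$target_volumes, provenance = "phantom")

  # compact cluster: the n voxels of the box closest to its centroid under
  # an elongated ellipsoidal metric (the LC runs rostro-caudally)
  cluster_in_box <- function(box, name) {
    n <- design$lc_cluster_voxels
    if (n > nrow(box))
      stop("cluster of ", n, " voxels cannot fit in box `", name,
           "` (", nrow(box), " voxels)", call. = FALSE)
    ctr <- colMeans(box)
    semi <- c(1.5, 1.5, 4.5)
    d <- ((box[, 1] - ctr[1]) * spacing[1] / semi[1])^2 +
      ((box[, 2] - ctr[2]) * spacing[2] / semi[2])^2 +
      ((box[, 3] - ctr[3]) * spacing[3] / semi[3])^2
    ord <- order(d, .linear_index(box, dimg))
    box[ord[seq_len(n)], , drop = FALSE]
  }
  true_left <- cluster_in_box(native_boxes$boxes$lc_left, "lc_left")
  true_right <- cluster_in_box(native_boxes$boxes$lc_right, "lc_right")

  arr <- array(design$background, dimg)
  arr <- .place_distractors(arr, native_boxes, design, dimg)
  arr[.linear_index(true_left, dimg)] <- design$background * contrast
  arr[.linear_index(true_right, dimg)] <- design$background * contrast
  if (design$noise_sigma > 0) {
    if (design$noise_model == "gaussian") {
      arr <- arr + array(stats::rnorm(prod(dimg), 0, design$noise_sigma),
                         dimg)
    } else {
      e1 <- array(stats::rnorm(prod(dimg), 0, design$noise_sigma), dimg)
      e2 <- array(stats::rnorm(prod(dimg), 0, design$noise_sigma), dimg)
      arr <- sqrt((arr + e1)^2 + e2^2)
    }
  }

  structure(list(subject_id = sprintf("S%03d", subject_index),
                 group = group,
                 tse_image = image_volume(arr, spacing, "native"),
                 transform = transform,
                 native_boxes = native_boxes,
                 template_boxes = tpl,
                 true_lc_voxels = list(left = true_left,
                                       right = true_right),
                 true_lc_contrast = contrast),
            class = "phantom_subject")
}

#' Generate an NBM phantom subject
#'
#' Draws a subject-specific template-to-native deformation (isotropic
#' scaling about the mask centroid at the group's scale factor with
#' log-normal between-subject jitter, composed with a smooth
#' divergence-free sinusoidal displacement with random phase) and pushes
#' the bilateral template mask through it side by side. The native masks
#' and the resulting ground-truth volume are recorded.
#'
#' @param design a \code{phantom_design}.
#' @param subject_index subject position in the cohort.
#' @param template_mask bilateral template mask (default the bundled
#'   synthetic template).
#' @param icv_mm3 intracranial volume; drawn from the covariate model when
#'   \code{NULL}.
#' @return a \code{phantom_subject} list with elements \code{deformation},
#'   \code{native_nbm_left}, \code{native_nbm_right},
#'   \code{true_nbm_volume_mm3}, \code{true_nbm_scale}, \code{icv_mm3}
#'   and \code{nbm_result}.
#' @export
generate_nbm_phantom <- function(design, subject_index,
                                 template_mask = NULL, icv_mm3 = NULL) {
  stopifnot(inherits(design, "phantom_design"))
  group <- .group_of_subject(design, subject_index)
  set.seed(.subject_seed(design$seed, subject_index, stage = 2L))
  if (is.null(template_mask)) template_mask <- synthetic_nbm_template()

  s <- design$nbm_scale_by_group[[group]] *
    exp(stats::rnorm(1L, 0, design$nbm_scale_sd))
  vox <- which(template_mask$data != 0, arr.ind = TRUE)
  ctr <- colMeans(.voxel_to_world(vox, template_mask$spacing))
  A <- diag(4)
  A[1:3, 1:3] <- diag(rep(s, 3))
  A[1:3, 4] <- ctr - s * ctr
  def <- deformation_sinusoidal(
    A, amplitude = design$nbm_sinusoid_amplitude,
    wavelength = design$nbm_sinusoid_wavelength,
    phase = stats::runif(3L, 0, 2 * pi))

  target_dim <- pmax(1L, as.integer(round(dim(template_mask$data) *
    template_mask$spacing / design$t1_voxel)))
  sides <- split_mask_sides(template_mask)
  left <- warp_mask(sides$left, def, target_dim, design$t1_voxel)
  right <- warp_mask(sides$right, def, target_dim, design$t1_voxel)
  if (is.null(icv_mm3)) {
    male <- stats::runif(1L) < design$covariate_model$male_frac[[group]]
    icv_mm3 <- stats::rnorm(1L,
      if (male) design$covariate_model$icv_male
      else design$covariate_model$icv_female,
      design$covariate_model$icv_sd)
  }
  res <- compute_nbm_volume(left, right, icv_mm3)
  structure(list(subject_id = sprintf("S%03d", subject_index),
                 group = group, deformation = def,
                 template_mask = template_mask,
                 native_nbm_left = left, native_nbm_right = right,
                 t1_grid_shape = target_dim,
                 true_nbm_scale = s,
                 true_nbm_volume_mm3 = res$vol_mean_mm3,
                 icv_mm3 = icv_mm3, nbm_result = res),
            class = "phantom_subject")
}

#' Generate a phantom cohort table
#'
#' Draws covariates (age, sex, ICV) per the covariate model, then draws
#' all measures and cognitive scores from a joint Gaussian constructed so
#' that, conditional on group, age and sex, the designed partial
#' correlations hold: measure = group mean + age slope x (age - 70) +
#' correlated residual. LC-I missingness is injected per group. With
#' \code{images = TRUE} the matching image phantoms are generated for
#' every subject (LC slab and NBM masks) and returned alongside.
#'
#' @param design a \code{phantom_design}.
#' @param images generate per-subject image phantoms as well (slow for
#'   large cohorts).
#' @return list with \code{cohort} (data frame: subject_id, group, age,
#'   sex, icv_mm3, one column per measure), \code{subjects} (list of
#'   \code{phantom_subject} or \code{NULL}) and \code{design}.
#' @export
generate_cohort <- function(design, images = FALSE) {
  stopifnot(inherits(design, "phantom_design"))
  set.seed(design$seed)
  labels <- design$group_labels
  groups <- rep(labels, design$n_per_group)
  n <- length(groups)
  cm <- design$covariate_model
  age <- stats::rnorm(n, cm$age_mean[groups], cm$age_sd[groups])
  male <- stats::runif(n) < cm$male_frac[groups]
  icv <- stats::rnorm(n, ifelse(male, cm$icv_male, cm$icv_female),
                      cm$icv_sd)

  mm <- design$measure_model
  meas_names <- colnames(mm$means)
  R <- design$residual_correlation
  Z <- matrix(stats::rnorm(n * length(meas_names)), n) %*% chol(R)
  resid <- sweep(Z, 2L, mm$sds[meas_names], `*`)
  meas <- mm$means[groups, , drop = FALSE] +
    outer(age - cm$age_ref, mm$age_slopes[meas_names]) + resid
  colnames(meas) <- meas_names

  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       group = factor(groups, levels = labels),
                       age = age,
                       sex = factor(ifelse(male, "M", "F"),
                                    levels = c("F", "M")),
                       icv_mm3 = icv, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(meas))

  for (g in labels) {
    m <- design$lc_missing_by_group[[g]]
    if (m > 0) {
      idx <- which(groups == g)
      cohort$lc_i[sample(idx, m)] <- NA_real_
    }
  }

  subjects <- NULL
  if (images) {
    template <- synthetic_nbm_template()
    subjects <- lapply(seq_len(n), function(i) {
      lc <- generate_lc_phantom(design, i)
      nbm <- generate_nbm_phantom(design, i, template_mask = template,
                                  icv_mm3 = cohort$icv_mm3[i])
      lc[setdiff(names(nbm), names(lc))] <- nbm[setdiff(names(nbm),
                                                        names(lc))]
      class(lc) <- "phantom_subject"
      lc
    })
  }
  list(cohort = cohort, subjects = subjects, design = design)
}
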