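#' Pipeline run configuration
#'
#' A run is driven either by a phantom design (synthetic end-to-end run)
#' or by a subject manifest (a data frame of per-subject file paths and
#' covariates); exactly one of the two must be given.
#'
#' Manifest columns: \code{subject_id}, \code{group}, \code{age},
#' \code{sex}, \code{icv_mm3}, and optional path columns
#' \code{tse_path} (TSE slab NIfTI), \code{lc_transform_path} (4x4 affine
#' text file, template to native), \code{nbm_transform_path} (4x4 affine
#' text or displacement-field NIfTI), \code{stats_lh}, \code{stats_rh},
#' \code{aseg} (regional statistics tables). Cognitive score columns are
#' carried through verbatim. A missing or unreadable path makes that
#' subject's corresponding measure missing-by-policy; downstream
#' statistics use listwise deletion.
#'
#' @param design a \code{phantom_design}, or \code{NULL}.
#' @param manifest a manifest data frame, or \code{NULL}.
#' @param out_dir output directory.
#' @param k,connectivity,formula LC extraction options.
#' @param interpolation mask warping interpolation.
#' @param nbm_template_path optional NIfTI path of a real NBM template
#'   mask (default: the bundled synthetic template).
#' @param voi_config path to a VOI YAML configuration.
#' @param plan an \code{analysis_plan}, or \code{NULL} to skip
#'   statistics.
#' @param seed integer seed recorded in provenance (phantom runs draw all
#'   randomness from the design's own seed).
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(design = NULL, manifest = NULL, out_dir = tempdir(),
                       k = 10L, connectivity = 26L,
                       formula = c("ratio", "contrast"),
                       interpolation = c("trilinear", "nearest"),
                       nbm_template_path = NULL,
                       voi_config = NULL,
                       plan = default_analysis_plan(),
                       seed = 1L) {
  if (is.null(design) == is.null(manifest))
    stop("exactly one of `design` or `manifest` must be supplied",
         call. = FALSE)
  structure(list(design = design, manifest = manifest, out_dir = out_dir,
                 k = as.integer(k), connectivity = as.integer(connectivity),
                 formula = match.arg(formula),
                 interpolation = match.arg(interpolation),
                 nbm_template_path = nbm_template_path,
                 voi_config = voi_config, plan = plan,
                 seed = as.integer(seed)),
            class = "run_config")
}

.measure_lc_subject <- function(subject, config) {
  res <- compute_lc_intensity(subject$tse_image, subject$native_boxes,
                              k = config$k,
                              connectivity = config$connectivity,
                              formula = config$formula)
  res
}

#' Run the full pipeline
#'
#' Phantom mode: generates the cohort table, then for every subject
#' builds the LC slab phantom, resamples the template boxes through the
#' subject transform, extracts LC-I, builds the NBM phantom, warps the
#' template mask and computes the ICV-normalized NBM volume; the measured
#' values replace the model-drawn \code{lc_i} / \code{nbm_vol_norm}
#' columns (designed LC-I missingness is applied to the measured values).
#' Manifest mode: reads each subject's files and computes whichever
#' measures its paths allow. In both modes the statistics plan is then
#' executed and the cohort CSV, result tables, family manifest and a
#' provenance record (seed, config hash, package version) are written to
#' \code{out_dir}. Re-running with an identical config reproduces
#' identical outputs; per-subject failures are collected in
#' \code{failures.json} without aborting the run.
#'
#' @param config a \code{run_config}.
#' @return a list of class \code{pipeline_result} with elements
#'   \code{cohort}, \code{results}, \code{failures}, \code{provenance}
#'   and \code{paths}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- list()
  note_failure <- function(subject_id, stage, err) {
    failures[[length(failures) + 1L]] <<- list(
      subject = subject_id, stage = stage,
      message = conditionMessage(err))
  }

  if (!is.null(config$design)) {
    gen <- generate_cohort(config$design, images = FALSE)
    cohort <- gen$cohort
    if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
    lc_missing <- is.na(cohort$lc_i)
    template <- if (is.null(config$nbm_template_path))
      synthetic_nbm_template()
    else read_image_volume(config$nbm_template_path, space = "template")
    cohort$nbm_vol_mm3 <- NA_real_
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      lc_i <- tryCatch({
        subj <- generate_lc_phantom(config$design, i)
        boxes <- resample_boxes(subj$template_boxes, subj$transform,
                                dim(subj$tse_image$data),
                                subj$tse_image$spacing)
        compute_lc_intensity(subj$tse_image, boxes, k = config$k,
                             connectivity = config$connectivity,
                             formula = config$formula)$lc_i
      }, error = function(e) { note_failure(sid, "lc_intensity", e)
        NA_real_ })
      cohort$lc_i[i] <- if (lc_missing[i]) NA_real_ else lc_i
      nbm <- tryCatch({
        generate_nbm_phantom(config$design, i, template_mask = template,
                             icv_mm3 = cohort$icv_mm3[i])$nbm_result
      }, error = function(e) { note_failure(sid, "nbm_volume", e); NULL })
      if (!is.null(nbm)) {
        cohort$nbm_vol_mm3[i] <- nbm$vol_mean_mm3
        cohort$nbm_vol_norm[i] <- nbm$vol_norm
      } else {
        cohort$nbm_vol_norm[i] <- NA_real_
      }
    }
  } else {
    cohort <- .run_manifest(config, note_failure)
  }
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)

  results <- NULL
  if (!is.null(config$plan))
    results <- run_analysis_plan(cohort, config$plan)

  paths <- list(cohort = file.path(config$out_dir, "cohort.csv"))
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  if (!is.null(results)) {
    paths$group_summary <- file.path(config$out_dir, "group_summary.csv")
    paths$ancova <- file.path(config$out_dir, "group_comparisons.csv")
    paths$correlations <- file.path(config$out_dir,
                                    "partial_correlations.csv")
    paths$r2_matrix <- file.path(config$out_dir, "r2_matrix.csv")
    paths$manifest <- file.path(config$out_dir, "test_manifest.json")
    utils::write.csv(results$group_summary, paths$group_summary,
                     row.names = FALSE)
    utils::write.csv(results$ancova, paths$ancova, row.names = FALSE)
    utils::write.csv(results$correlations, paths$correlations,
                     row.names = FALSE)
    utils::write.csv(results$r2_matrix, paths$r2_matrix)
    jsonlite::write_json(results$manifest, paths$manifest,
                         auto_unbox = FALSE, digits = NA)
  }
  provenance <- list(
    package = "lcnbm",
    version = as.character(utils::packageVersion("lcnbm")),
    seed = config$seed,
    config_hash = .config_hash(config),
    timestamp_omitted = "outputs are content-addressed, not timestamped",
    mode = if (is.null(config$design)) "manifest" else "phantom")
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE)
  if (length(failures)) {
    paths$failures <- file.path(config$out_dir, "failures.json")
    jsonlite::write_json(failures, paths$failures, auto_unbox = TRUE)
  }
  structure(list(cohort = cohort, results = results, failures = failures,
                 provenance = provenance, paths = paths),
            class = "pipeline_result")
}

# md5 of the deparsed config (stable across identical configs)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

.run_manifest <- function(config, note_failure) {
  man <- config$manifest
  if (is.null(man) || nrow(man) == 0L) stop("empty cohort", call. = FALSE)
  need <- c("subject_id", "group", "age", "sex", "icv_mm3")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  template <- if (is.null(config$nbm_template_path))
    synthetic_nbm_template()
  else read_image_volume(config$nbm_template_path, space = "template")
  defs <- if (is.null(config$voi_config)) default_voi_definitions()
  else default_voi_definitions(config$voi_config)
  tpl_boxes <- NULL

  path_ok <- function(p) !is.null(p) && !is.na(p) && nzchar(p) &&
    file.exists(p)
  get_path <- function(i, col) if (col %in% names(man)) man[[col]][i]
  else NA_character_

  rows <- lapply(seq_len(nrow(man)), function(i) {
    sid <- man$subject_id[i]
    row <- as.list(man[i, setdiff(names(man),
                                  grep("_path$|^stats_|^aseg$",
                                       names(man), value = TRUE)),
                   drop = FALSE])
    row$lc_i <- NA_real_
    row$nbm_vol_mm3 <- NA_real_
    row$nbm_vol_norm <- NA_real_
    tse <- get_path(i, "tse_path")
    if (path_ok(tse)) {
      row$lc_i <- tryCatch({
        img <- read_image_volume(tse)
        if (is.null(tpl_boxes))
          tpl_boxes <<- build_template_boxes(img$spacing)
        tr_path <- get_path(i, "lc_transform_path")
        tr <- if (path_ok(tr_path)) read_affine_transform(tr_path)
        else NULL
        boxes <- resample_boxes(tpl_boxes, tr, dim(img$data), img$spacing)
        compute_lc_intensity(img, boxes, k = config$k,
                             connectivity = config$connectivity,
                             formula = config$formula)$lc_i
      }, error = function(e) { note_failure(sid, "lc_intensity", e)
        NA_real_ })
    }
    nbm_tr <- get_path(i, "nbm_transform_path")
    if (path_ok(nbm_tr)) {
      res <- tryCatch({
        tr <- if (grepl("\\.nii(\\.gz)?$", nbm_tr))
          read_displacement_field(nbm_tr)
        else read_affine_transform(nbm_tr)
        sides <- split_mask_sides(template)
        left <- warp_mask(sides$left, tr,
                          interpolation = config$interpolation)
        right <- warp_mask(sides$right, tr,
                           interpolation = config$interpolation)
        compute_nbm_volume(left, right, man$icv_mm3[i])
      }, error = function(e) { note_failure(sid, "nbm_volume", e); NULL })
      if (!is.null(res)) {
        row$nbm_vol_mm3 <- res$vol_mean_mm3
        row$nbm_vol_norm <- res$vol_norm
      }
    }
    stats_files <- c(get_path(i, "stats_lh"), get_path(i, "stats_rh"),
                     get_path(i, "aseg"))
    stats_files <- stats_files[vapply(stats_files, path_ok, logical(1))]
    if (length(stats_files)) {
      vois <- tryCatch({
        tab <- parse_region_stats(stats_files, subject_id = sid)
        compute_composite_vois(tab, defs, icv_mm3 = man$icv_mm3[i])
      }, error = function(e) { note_failure(sid, "roi_composites", e)
        NULL })
      if (!is.null(vois)) {
        for (nm in c("temporal_meta", "lateral_temporal",
                     "lateral_parietal", "medial_parietal", "frontal"))
          if (nm %in% names(vois))
            row[[paste0("ct_", nm)]] <- unname(vois[nm])
        for (nm in c("hippocampus", "amygdala")) {
          norm <- paste0(nm, "_norm")
          if (norm %in% names(vois)) row[[nm]] <- unname(vois[norm])
        }
        if ("entorhinal_volume_norm" %in% names(vois))
          row$entorhinal <- unname(vois["entorhinal_volume_norm"])
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(nms, names(r))] <- NA
    r[nms]
  })
  cohort <- do.call(rbind, rows)
  cohort$group <- factor(cohort$group)
  cohort$sex <- factor(cohort$sex)
  cohort
}
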