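#' Parse regional cortical statistics tables
#'
#' Reads per-hemisphere cortical parcellation tables and subcortical
#' segmentation tables in the aparc/aseg dialect: '#'-prefixed header
#' lines, a \code{# ColHeaders ...} line naming the columns, and
#' whitespace-delimited data rows. Cortical tables must provide
#' \code{StructName}, \code{SurfArea}, \code{GrayVol} and \code{ThickAvg};
#' subcortical tables must provide \code{StructName} and
#' \code{Volume_mm3}, with the hemisphere taken from \code{Left-} /
#' \code{Right-} name prefixes. Unknown region names are preserved
#' verbatim. An \code{# hemi lh} / \code{# hemi rh} header line sets the
#' hemisphere of a cortical table.
#'
#' @param files character vector of file paths (any mix of cortical and
#'   subcortical tables, typically lh/rh aparc plus one aseg file).
#' @param subject_id optional subject identifier attached to the table.
#' @return a \code{region_table} data frame with columns \code{hemi}
#'   ("lh"/"rh"), \code{region}, \code{volume_mm3}, \code{thickness_mm},
#'   \code{surf_area_mm2}; the intracranial volume is attached as
#'   attribute \code{icv_mm3} when an \code{EstimatedTotalIntraCranialVol}
#'   measure line is present. Thickness outside (0, 6) mm triggers a
#'   warning.
#' @export
parse_region_stats <- function(files, subject_id = NA_character_) {
  rows <- list()
  icv <- NA_real_
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    hdr <- grep("^#", lines)
    hemi <- NA_character_
    colheaders <- NULL
    for (h in lines[hdr]) {
      if (grepl("^#\\s*hemi\\s+", h))
        hemi <- sub("^#\\s*hemi\\s+", "", h)
      if (grepl("^#\\s*ColHeaders\\s+", h))
        colheaders <- strsplit(sub("^#\\s*ColHeaders\\s+", "", h),
                               "\\s+")[[1]]
      if (grepl("EstimatedTotalIntraCranialVol", h)) {
        parts <- strsplit(h, ",")[[1]]
        num <- suppressWarnings(as.numeric(trimws(parts)))
        if (any(!is.na(num))) icv <- num[which(!is.na(num))[1L]]
      }
    }
    if (is.null(colheaders))
      stop("no `# ColHeaders` line in ", f, call. = FALSE)
    data_idx <- setdiff(seq_along(lines), hdr)
    data_idx <- data_idx[nzchar(trimws(lines[data_idx]))]
    if ("ThickAvg" %in% colheaders) {
      need <- c("StructName", "SurfArea", "GrayVol", "ThickAvg")
    } else if ("Volume_mm3" %in% colheaders) {
      need <- c("StructName", "Volume_mm3")
    } else {
      stop("file ", f, " has neither a ThickAvg nor a Volume_mm3 column",
           call. = FALSE)
    }
    miss <- setdiff(need, colheaders)
    if (length(miss))
      stop("file ", f, " is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (i in data_idx) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) != length(colheaders))
        stop("malformed row at line ", i, " of ", f, ": expected ",
             length(colheaders), " fields, found ", length(tok),
             call. = FALSE)
      names(tok) <- colheaders
      if ("ThickAvg" %in% colheaders) {
        num <- suppressWarnings(as.numeric(
          tok[c("SurfArea", "GrayVol", "ThickAvg")]))
        if (any(is.na(num)))
          stop("malformed row at line ", i, " of ", f,
               ": non-numeric measurement", call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          hemi = hemi, region = tok[["StructName"]],
          volume_mm3 = num[2L], thickness_mm = num[3L],
          surf_area_mm2 = num[1L], stringsAsFactors = FALSE)
      } else {
        vol <- suppressWarnings(as.numeric(tok[["Volume_mm3"]]))
        if (is.na(vol))
          stop("malformed row at line ", i, " of ", f,
               ": non-numeric volume", call. = FALSE)
        nm <- tok[["StructName"]]
        h2 <- if (startsWith(nm, "Left-")) "lh"
        else if (startsWith(nm, "Right-")) "rh" else NA_character_
        region <- sub("^(Left|Right)-", "", nm)
        rows[[length(rows) + 1L]] <- data.frame(
          hemi = h2, region = region, volume_mm3 = vol,
          thickness_mm = NA_real_, surf_area_mm2 = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- !is.na(out$thickness_mm) &
    (out$thickness_mm <= 0 | out$thickness_mm >= 6)
  if (any(bad))
    warning(sum(bad), " region(s) with thickness outside the (0, 6) mm ",
            "plausibility band", call. = FALSE)
  if (any(out$volume_mm3 < 0, na.rm = TRUE))
    stop("negative volumes in region table", call. = FALSE)
  attr(out, "subject_id") <- subject_id
  attr(out, "icv_mm3") <- icv
  class(out) <- c("region_table", "data.frame")
  out
}

#' Write a region table in the aparc/aseg dialect
#'
#' Serializes a \code{region_table} to per-hemisphere cortical files plus
#' one subcortical file, in the same dialect \code{parse_region_stats}
#' reads, at full numeric precision (so a write/parse round-trip
#' reproduces the table).
#'
#' @param table a \code{region_table}.
#' @param dir output directory.
#' @param prefix file name prefix (default \code{"subject"}).
#' @param icv_mm3 optional intracranial volume recorded as a measure line.
#' @return character vector of the written paths.
#' @export
write_region_stats <- function(table, dir, prefix = "subject",
                               icv_mm3 = attr(table, "icv_mm3")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) vapply(x, function(v) format(v, digits = 17),
                            character(1))
  paths <- character(0)
  cortical <- !is.na(table$thickness_mm)
  for (h in c("lh", "rh")) {
    sub <- table[cortical & table$hemi == h, , drop = FALSE]
    if (nrow(sub) == 0L) next
    p <- file.path(dir, paste0(prefix, ".", h, ".aparc.stats"))
    lines <- c(paste0("# Table of cortical parcellation statistics"),
               paste0("# hemi ", h),
               "# ColHeaders StructName SurfArea GrayVol ThickAvg",
               paste(sub$region, fmt(sub$surf_area_mm2),
                     fmt(sub$volume_mm3), fmt(sub$thickness_mm)))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  sub <- table[!cortical, , drop = FALSE]
  if (nrow(sub) > 0L) {
    p <- file.path(dir, paste0(prefix, ".aseg.stats"))
    nm <- paste0(ifelse(sub$hemi == "lh", "Left-", "Right-"), sub$region)
    lines <- c("# Table of subcortical segmentation statistics",
               if (!is.null(icv_mm3) && !is.na(icv_mm3))
                 paste0("# Measure EstimatedTotalIntraCranialVol, eTIV, ",
                        "Estimated Total Intracranial Volume, ",
                        format(icv_mm3, digits = 17), ", mm^3"),
               "# ColHeaders Index StructName Volume_mm3",
               paste(seq_len(nrow(sub)), nm, fmt(sub$volume_mm3)))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  paths
}

#' Composite VOI definition
#'
#' @param name VOI name.
#' @param members member region names (aparc/aseg vocabulary).
#' @param measure \code{"thickness"} or \code{"volume"}.
#' @return a \code{voi_definition}.
#' @export
voi_definition <- function(name, members, measure = c("thickness",
                                                      "volume")) {
  measure <- match.arg(measure)
  if (length(members) == 0L)
    stop("VOI `", name, "` has no member regions", call. = FALSE)
  structure(list(name = name, members = as.character(members),
                 measure = measure), class = "voi_definition")
}

#' Default composite VOI definitions
#'
#' Loads the shipped VOI configuration: the temporal meta-VOI (entorhinal,
#' parahippocampal, fusiform, inferior and middle temporal cortex) and the
#' lateral temporal, lateral parietal, medial parietal and frontal lobar
#' sets, plus the medial-temporal volume VOIs (hippocampus, amygdala,
#' entorhinal). The member lists are an editable YAML file under
#' \code{inst/extdata}, not hard-coded.
#'
#' @param path path to a VOI YAML configuration (default: the shipped
#'   file).
#' @return named list of \code{voi_definition} objects.
#' @export
default_voi_definitions <- function(path = system.file(
  "extdata", "voi_definitions.yaml", package = "lcnbm")) {
  cfg <- yaml::read_yaml(path)
  defs <- lapply(names(cfg), function(nm)
    voi_definition(nm, cfg[[nm]]$members, cfg[[nm]]$measure))
  names(defs) <- names(cfg)
  defs
}

#' Compute composite VOI measures from a region table
#'
#' Thickness composites are the surface-area-weighted mean of member
#' thicknesses within each hemisphere (plain mean when
#' \code{weighted = FALSE}), then averaged across hemispheres. Volume
#' composites are the sum of member volumes per hemisphere, then averaged
#' across hemispheres; when \code{icv_mm3} is given, volume composites are
#' additionally normalized to ICV with the per-mil convention (matching
#' the NBM normalization).
#'
#' @param table a \code{region_table}.
#' @param defs list of \code{voi_definition}s (default the shipped set).
#' @param weighted surface-area weighting for thickness composites.
#' @param icv_mm3 optional ICV for volume normalization.
#' @return named numeric vector of composite measures (volume VOIs carry
#'   a \code{"<name>_norm"} entry as well when \code{icv_mm3} is given).
#' @export
compute_composite_vois <- function(table, defs = default_voi_definitions(),
                                   weighted = TRUE, icv_mm3 = NULL) {
  stopifnot(inherits(table, "data.frame"))
  out <- numeric(0)
  for (def in defs) {
    per_hemi <- vapply(c("lh", "rh"), function(h) {
      sub <- table[table$hemi == h & table$region %in% def$members, ,
                   drop = FALSE]
      missing <- setdiff(def$members, sub$region)
      if (length(missing))
        stop("VOI `", def$name, "`: member region(s) missing in ", h,
             ": ", paste(missing, collapse = ", "), call. = FALSE)
      if (def$measure == "thickness") {
        if (weighted)
          stats::weighted.mean(sub$thickness_mm, sub$surf_area_mm2)
        else mean(sub$thickness_mm)
      } else {
        sum(sub$volume_mm3)
      }
    }, numeric(1))
    val <- mean(per_hemi)
    out[def$name] <- val
    if (def$measure == "volume" && !is.null(icv_mm3) && !is.na(icv_mm3))
      out[paste0(def$name, "_norm")] <- val / icv_mm3 * 1000
  }
  out
}

# Desikan-Killiany cortical parcel vocabulary
.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
  "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
  "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
  "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
  "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
  "superiorfrontal", "superiorparietal", "superiortemporal",
  "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
  "insula")

#' Synthetic regional statistics table
#'
#' Generates a plausible per-region table (34 cortical parcels per
#' hemisphere plus hippocampus and amygdala subcortical volumes) for
#' phantom subjects: thickness ~ 2.5 mm, parcel areas and volumes on
#' FreeSurfer-like scales, with seeded Gaussian jitter and an optional
#' global atrophy factor. Used to exercise the parser, the composites and
#' manifest-driven pipelines; it makes no claim to anatomical realism.
#'
#' @param subject_id subject identifier.
#' @param seed integer RNG seed.
#' @param atrophy multiplicative factor (< 1 thins cortex and shrinks
#'   volumes).
#' @param icv_mm3 intracranial volume recorded on the table.
#' @return a \code{region_table}.
#' @export
synthetic_region_stats <- function(subject_id = "S001", seed = 1,
                                   atrophy = 1, icv_mm3 = 1.45e6) {
  set.seed(as.integer(seed))
  rows <- list()
  for (h in c("lh", "rh")) {
    area <- stats::rlnorm(length(.dk_regions), log(1500), 0.4)
    thick <- (2.5 + stats::rnorm(length(.dk_regions), 0, 0.15)) * atrophy
    vol <- area * thick
    rows[[h]] <- data.frame(hemi = h, region = .dk_regions,
                            volume_mm3 = vol, thickness_mm = thick,
                            surf_area_mm2 = area, stringsAsFactors = FALSE)
  }
  sub <- expand.grid(hemi = c("lh", "rh"),
                     region = c("Hippocampus", "Amygdala"),
                     stringsAsFactors = FALSE)
  sub$volume_mm3 <- c(4000, 4000, 1600, 1600) * atrophy *
    exp(stats::rnorm(4, 0, 0.05))
  sub$thickness_mm <- NA_real_
  sub$surf_area_mm2 <- NA_real_
  out <- rbind(rows$lh, rows$rh, sub)
  rownames(out) <- NULL
  attr(out, "subject_id") <- subject_id
  attr(out, "icv_mm3") <- icv_mm3
  class(out) <- c("region_table", "data.frame")
  out
}
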