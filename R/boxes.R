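#' Bounding-box sets for locus coeruleus intensity extraction
#'
#' The LC-I computation uses three boxes defined on a brainstem template:
#' a rostral pontomesencephalic reference region with a target volume of
#' 6200 mm^3, and left / right boxes containing the coeruleus-subcoeruleus
#' complexes with target volumes of 700 mm^3 each. A \code{box_set} holds
#' the three boxes as voxel index sets on a common grid, together with the
#' grid geometry and a space tag.
#'
#' @name box_set
NULL

.new_box_set <- function(boxes, grid_dim, spacing, space,
                         target_volumes, provenance = "constructed") {
  vv <- prod(spacing)
  achieved <- vapply(boxes, function(b) nrow(b) * vv, numeric(1))
  structure(list(boxes = boxes, grid_dim = as.integer(grid_dim),
                 spacing = as.numeric(spacing), space = space,
                 target_volumes = target_volumes,
                 achieved_volumes = achieved,
                 provenance = provenance),
            class = "box_set")
}

#' @export
print.box_set <- function(x, ...) {
  cat("<box_set> space:", x$space, " grid:",
      paste(x$grid_dim, collapse = " x "), "@",
      paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  for (nm in names(x$boxes))
    cat(sprintf("  %-10s %6d voxels  %8.2f mm^3\n", nm, nrow(x$boxes[[nm]]),
                x$achieved_volumes[[nm]]))
  invisible(x)
}

# a cuboid voxel set of (approximately) n voxels: full x-y slices stacked in
# z with the last slice partially filled in x-fastest order, anchored at
# `origin`; physical shape is chosen close to a cube of the target volume
.box_voxels <- function(n, spacing, origin) {
  side <- (n * prod(spacing))^(1 / 3)
  nx <- max(1L, round(side / spacing[1L]))
  ny <- max(1L, round(side / spacing[2L]))
  nz <- max(1L, ceiling(n / (nx * ny)))
  rel <- .from_linear(seq_len(n), c(nx, ny, nz))
  sweep(rel, 2L, as.integer(origin) - 1L, `+`)
}

.box_extent <- function(n, spacing) {
  side <- (n * prod(spacing))^(1 / 3)
  nx <- max(1L, round(side / spacing[1L]))
  ny <- max(1L, round(side / spacing[2L]))
  nz <- max(1L, ceiling(n / (nx * ny)))
  c(nx, ny, nz)
}

#' Build the template bounding boxes
#'
#' Constructs the reference and bilateral LC boxes on a template grid.
#' Exact target volumes are generally unreachable with whole voxels, so
#' each box contains \code{round(target / voxel_volume)} voxels laid out
#' as a near-cubic cuboid whose final slice may be partially filled; the
#' achieved volume is always within half a voxel volume of the target.
#' The left and right LC boxes are mirror images about the midsagittal
#' plane of the grid, placed anterior to the reference region so the three
#' boxes are pairwise disjoint.
#'
#' @param voxel_spacing voxel size in mm (default the turbo-spin-echo slab
#'   resolution, 0.4 x 0.4 x 3 mm).
#' @param geometry list of geometry options: \code{fov_mm} field of view
#'   in mm (default \code{c(38.4, 38.4, 60)}), \code{reference_volume} and
#'   \code{lc_volume} targets in mm^3 (defaults 6200 and 700), and
#'   \code{min_voxels} the minimum LC box size in voxels (default 10, the
#'   selection size).
#' @return a \code{box_set} in template space with boxes
#'   \code{reference}, \code{lc_left} and \code{lc_right}.
#' @export
build_template_boxes <- function(voxel_spacing = c(0.4, 0.4, 3),
                                 geometry = list()) {
  spacing <- .check_positive_triple(voxel_spacing, "voxel_spacing")
  geo <- utils::modifyList(list(fov_mm = c(38.4, 38.4, 60),
                                reference_volume = 6200,
                                lc_volume = 700,
                                min_voxels = 10L), geometry)
  grid_dim <- pmax(2L, as.integer(round(geo$fov_mm / spacing)))
  vv <- prod(spacing)
  n_ref <- max(1L, round(geo$reference_volume / vv))
  n_lc <- round(geo$lc_volume / vv)
  if (n_lc < geo$min_voxels)
    stop("voxel spacing too coarse: a ", geo$lc_volume,
         " mm^3 LC box would contain only ", n_lc, " voxels (< ",
         geo$min_voxels, ")", call. = FALSE)

  ext_ref <- .box_extent(n_ref, spacing)
  ext_lc <- .box_extent(n_lc, spacing)

  # left LC box in the left half of the grid, anterior (low y); reference
  # centred in x, posterior (high y)
  lc_x0 <- max(1L, floor(grid_dim[1L] * 0.28 - ext_lc[1L] / 2))
  lc_y0 <- max(1L, floor(grid_dim[2L] * 0.30 - ext_lc[2L] / 2))
  lc_z0 <- max(1L, floor((grid_dim[3L] - ext_lc[3L]) / 2) + 1L)
  ref_x0 <- max(1L, floor((grid_dim[1L] - ext_ref[1L]) / 2) + 1L)
  ref_y0 <- max(1L, floor(grid_dim[2L] * 0.70 - ext_ref[2L] / 2))
  ref_z0 <- max(1L, floor((grid_dim[3L] - ext_ref[3L]) / 2) + 1L)

  if (lc_x0 + ext_lc[1L] - 1L > floor(grid_dim[1L] / 2))
    stop("grid too small: left LC box crosses the midsagittal plane",
         call. = FALSE)
  if (lc_y0 + ext_lc[2L] - 1L >= ref_y0)
    stop("grid too small: LC boxes would overlap the reference box",
         call. = FALSE)
  if (ref_x0 + ext_ref[1L] - 1L > grid_dim[1L] ||
      ref_y0 + ext_ref[2L] - 1L > grid_dim[2L] ||
      ref_z0 + ext_ref[3L] - 1L > grid_dim[3L] ||
      lc_z0 + ext_lc[3L] - 1L > grid_dim[3L])
    stop("grid too small to hold the reference box; enlarge `fov_mm`",
         call. = FALSE)

  lc_left <- .box_voxels(n_lc, spacing, c(lc_x0, lc_y0, lc_z0))
  # mirror about the midsagittal plane x = (nx + 1) / 2
  lc_right <- lc_left
  lc_right[, 1L] <- grid_dim[1L] + 1L - lc_left[, 1L]
  reference <- .box_voxels(n_ref, spacing, c(ref_x0, ref_y0, ref_z0))

  .new_box_set(list(reference = reference, lc_left = lc_left,
                    lc_right = lc_right),
               grid_dim, spacing, "template",
               c(reference = geo$reference_volume, lc_left = geo$lc_volume,
                 lc_right = geo$lc_volume))
}

# logical membership mask for one box on its grid
.box_mask <- function(box, grid_dim) {
  m <- array(FALSE, grid_dim)
  m[.linear_index(box, grid_dim)] <- TRUE
  m
}

#' Resample template boxes onto a native image grid
#'
#' Each native-grid voxel is labelled by nearest-neighbour pull-back: the
#' voxel centre is mapped to template space through the inverse of the
#' template-to-native transform, and the voxel joins a box when its
#' template pre-image falls inside that box. Because the template boxes
#' are disjoint and the pull-back assigns one template voxel per native
#' voxel, the resampled boxes are disjoint by construction.
#'
#' @param boxes a template-space \code{box_set}.
#' @param transform a \code{deformation_field} (template to native) or a
#'   4x4 affine matrix; \code{NULL} means identity.
#' @param target_grid_dim native grid dimensions.
#' @param target_spacing native voxel spacing in mm.
#' @return a native-space \code{box_set}.
#' @export
resample_boxes <- function(boxes, transform, target_grid_dim,
                           target_spacing) {
  stopifnot(inherits(boxes, "box_set"))
  if (is.matrix(transform)) transform <- deformation_affine(transform)
  target_grid_dim <- as.integer(target_grid_dim)
  target_spacing <- .check_positive_triple(target_spacing, "target_spacing")

  n_vox <- prod(target_grid_dim)
  vox <- .from_linear(seq_len(n_vox), target_grid_dim)
  world <- .voxel_to_world(vox, target_spacing)
  pre <- if (is.null(transform)) world else
    deform_points_inverse(transform, world)
  tvox <- round(.world_to_voxel(pre, boxes$spacing))
  inside <- tvox[, 1L] >= 1 & tvox[, 1L] <= boxes$grid_dim[1L] &
    tvox[, 2L] >= 1 & tvox[, 2L] <= boxes$grid_dim[2L] &
    tvox[, 3L] >= 1 & tvox[, 3L] <= boxes$grid_dim[3L]

  tlin <- rep(NA_real_, n_vox)
  tlin[inside] <- .linear_index(tvox[inside, , drop = FALSE], boxes$grid_dim)

  out <- vector("list", length(boxes$boxes))
  names(out) <- names(boxes$boxes)
  for (nm in names(boxes$boxes)) {
    mask <- .box_mask(boxes$boxes[[nm]], boxes$grid_dim)
    hit <- inside & mask[tlin]
    hit[is.na(hit)] <- FALSE
    if (!any(hit))
      stop("resampled box `", nm, "` is empty on the target grid",
           call. = FALSE)
    out[[nm]] <- vox[hit, , drop = FALSE]
  }
  .new_box_set(out, target_grid_dim, target_spacing, "native",
               boxes$target_volumes, provenance = "resampled")
}
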