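#' Synthetic bilateral NBM template mask
#'
#' A stand-in for an atlas-derived nucleus basalis of Meynert (Ch4) mask:
#' two mirror-symmetric ellipsoidal blobs (~350 mm^3 each at the default
#' 1 mm spacing) on an otherwise empty template grid. It reproduces the
#' geometry the volumetry pipeline needs (a small bilateral basal
#' forebrain structure) without shipping any third-party atlas; a real
#' atlas mask in NIfTI form can be supplied wherever this template is
#' accepted.
#'
#' @param grid_dim template grid dimensions (default \code{c(48, 56, 40)}).
#' @param spacing template voxel spacing in mm (default 1 mm isotropic).
#' @param semi_axes ellipsoid semi-axes in mm (default \code{c(3, 7, 4)}).
#' @return a binary \code{image_volume} in template space
#'   (\code{side = "bilateral"}).
#' @export
synthetic_nbm_template <- function(grid_dim = c(48, 56, 40),
                                   spacing = c(1, 1, 1),
                                   semi_axes = c(3, 7, 4)) {
  grid_dim <- as.integer(grid_dim)
  spacing <- .check_positive_triple(spacing, "spacing")
  arr <- array(0, grid_dim)
  centres <- rbind(c(0.35, 0.5, 0.5), c(0.65, 0.5, 0.5))
  vox <- .from_linear(seq_len(prod(grid_dim)), grid_dim)
  world <- .voxel_to_world(vox, spacing)
  for (i in 1:2) {
    c_mm <- (centres[i, ] * grid_dim - 1) * spacing
    d2 <- ((world[, 1] - c_mm[1]) / semi_axes[1])^2 +
      ((world[, 2] - c_mm[2]) / semi_axes[2])^2 +
      ((world[, 3] - c_mm[3]) / semi_axes[3])^2
    arr[d2 <= 1] <- 1
  }
  image_volume(arr, spacing = spacing, space = "template",
               side = "bilateral")
}

#' Split a bilateral mask into left and right sides
#'
#' Splits at the midsagittal plane of the grid (x below / above
#' \code{(nx + 1) / 2}).
#'
#' @param mask a bilateral binary \code{image_volume}.
#' @return list with \code{left} and \code{right} \code{image_volume}s.
#' @export
split_mask_sides <- function(mask) {
  stopifnot(inherits(mask, "image_volume"))
  d <- dim(mask$data)
  mid <- (d[1L] + 1) / 2
  left <- mask$data
  right <- mask$data
  xs <- seq_len(d[1L])
  left[xs >= mid, , ] <- 0
  right[xs <= mid, , ] <- 0
  list(left = image_volume(left, mask$spacing, mask$space, side = "left"),
       right = image_volume(right, mask$spacing, mask$space, side = "right"))
}

#' Warp a template mask to native space
#'
#' Resamples a (binary or probabilistic) template mask onto a native grid
#' through a template-to-native transform, mirroring the atlas-to-subject
#' step of NBM volumetry: each native voxel centre is pulled back to
#' template space through the inverse map and the mask is interpolated
#' there. Trilinear interpolation of the binary values followed by a 0.5
#' threshold is the default (it yields smoother volume estimates under
#' small deformations); nearest-neighbour is available.
#'
#' @param template_mask an \code{image_volume} holding the mask.
#' @param inverse_transform a \code{deformation_field} mapping template to
#'   native space (the inverse of a native-to-template normalization), or
#'   a 4x4 affine matrix; \code{NULL} means identity.
#' @param target_grid_dim native grid dimensions (default: template grid).
#' @param target_spacing native voxel spacing (default: template spacing).
#' @param interpolation \code{"trilinear"} (then thresholded) or
#'   \code{"nearest"}.
#' @param threshold binarization threshold for trilinear interpolation.
#' @return a binary \code{image_volume} in native space.
#' @export
warp_mask <- function(template_mask, inverse_transform,
                      target_grid_dim = NULL, target_spacing = NULL,
                      interpolation = c("trilinear", "nearest"),
                      threshold = 0.5) {
  stopifnot(inherits(template_mask, "image_volume"))
  interpolation <- match.arg(interpolation)
  if (is.matrix(inverse_transform))
    inverse_transform <- deformation_affine(inverse_transform)
  if (is.null(target_grid_dim)) target_grid_dim <- dim(template_mask$data)
  if (is.null(target_spacing)) target_spacing <- template_mask$spacing
  target_grid_dim <- as.integer(target_grid_dim)
  target_spacing <- .check_positive_triple(target_spacing, "target_spacing")

  vox <- .from_linear(seq_len(prod(target_grid_dim)), target_grid_dim)
  world <- .voxel_to_world(vox, target_spacing)
  pre <- if (is.null(inverse_transform)) world else
    deform_points_inverse(inverse_transform, world)
  tvox <- .world_to_voxel(pre, template_mask$spacing)
  vals <- if (interpolation == "trilinear")
    .sample_trilinear(template_mask$data, tvox)
  else {
    v <- .sample_nearest(template_mask$data, tvox)
    v[is.na(v)] <- 0
    v
  }
  out <- array(as.numeric(vals >= threshold), target_grid_dim)
  if (sum(out) == 0)
    stop("warped mask is empty on the target grid", call. = FALSE)
  image_volume(out, spacing = target_spacing, space = "native",
               side = template_mask$side)
}

#' NBM volume from native-space side masks
#'
#' Computes left and right volumes as voxel count times voxel volume,
#' their side average, and the average normalized to intracranial volume.
#' The normalized value uses the per-mil convention
#' \code{vol_mean / icv * 1000}; the raw mm^3 values are always reported
#' alongside.
#'
#' @param mask_left,mask_right binary native-space \code{image_volume}s.
#' @param icv_mm3 intracranial volume in mm^3 (must be positive).
#' @return an object of class \code{nbm_result} with elements
#'   \code{vol_left_mm3}, \code{vol_right_mm3}, \code{vol_mean_mm3},
#'   \code{icv_mm3} and \code{vol_norm}.
#' @export
compute_nbm_volume <- function(mask_left, mask_right, icv_mm3) {
  stopifnot(inherits(mask_left, "image_volume"),
            inherits(mask_right, "image_volume"))
  if (!is.finite(icv_mm3) || icv_mm3 <= 0)
    stop("`icv_mm3` must be a positive volume in mm^3", call. = FALSE)
  vol_side <- function(mask, side) {
    n <- sum(mask$data != 0)
    if (n == 0) stop("empty ", side, " NBM mask", call. = FALSE)
    n * voxel_volume(mask)
  }
  vl <- vol_side(mask_left, "left")
  vr <- vol_side(mask_right, "right")
  vm <- (vl + vr) / 2
  structure(list(vol_left_mm3 = vl, vol_right_mm3 = vr, vol_mean_mm3 = vm,
                 icv_mm3 = icv_mm3, vol_norm = vm / icv_mm3 * 1000),
            class = "nbm_result")
}

#' @export
print.nbm_result <- function(x, ...) {
  cat(sprintf(paste0("<nbm_result> L %.1f mm^3, R %.1f mm^3, mean %.1f",
                     " mm^3, ICV-normalized %.4f (per mil)\n"),
              x$vol_left_mm3, x$vol_right_mm3, x$vol_mean_mm3, x$vol_norm))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary \code{image_volume}s on the same grid.
#' @return the Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "image_volume"), inherits(b, "image_volume"),
            all(dim(a$data) == dim(b$data)))
  am <- a$data != 0
  bm <- b$data != 0
  2 * sum(am & bm) / (sum(am) + sum(bm))
}
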