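#' 3-D image volume container
#'
#' A minimal carrier for a 3-D intensity grid together with its voxel
#' spacing. World coordinates are defined by a diagonal grid-to-world
#' affine: the centre of voxel \code{(1,1,1)} sits at world origin
#' \code{(0,0,0)} and axes are aligned with the grid, so the centre of
#' voxel \code{(i,j,k)} is at \code{(i-1, j-1, k-1) * spacing} mm. This is
#' the carrier used for turbo-spin-echo slabs, 3D-T1 volumes and binary
#' masks throughout the package.
#'
#' @param data numeric 3-D array of intensities (or 0/1 for masks).
#' @param spacing voxel size in mm along x, y, z.
#' @param space character space tag, e.g. \code{"template"} or
#'   \code{"native"}.
#' @param side for masks, one of \code{"left"}, \code{"right"},
#'   \code{"bilateral"} or \code{NA}.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), space = "native",
                         side = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- .check_positive_triple(spacing, "spacing")
  structure(list(data = data, spacing = spacing, space = space, side = side),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = " x "),
      " mm, space: ", x$space, "\n", sep = "")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param x an \code{image_volume} or a spacing triple.
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(x) {
  if (inherits(x, "image_volume")) prod(x$spacing) else prod(as.numeric(x))
}

# world coordinates (mm) of voxel centres given 1-based voxel indices
.voxel_to_world <- function(vox, spacing) {
  sweep(vox - 1, 2L, spacing, `*`)
}

.world_to_voxel <- function(world, spacing) {
  sweep(world, 2L, spacing, `/`) + 1
}

#' Read a NIfTI file into an image volume
#'
#' @param path path to a NIfTI file.
#' @param space space tag to attach.
#' @return an \code{image_volume}.
#' @export
read_image_volume <- function(path, space = "native") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI image: ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  image_volume(arr, spacing = spacing, space = space)
}

#' Write an image volume to a NIfTI file
#'
#' @param vol an \code{image_volume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
write_image_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# trilinear sampling of a 3-D array at continuous 1-based voxel coordinates;
# points outside the grid contribute 0
.sample_trilinear <- function(arr, pts) {
  d <- dim(arr)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(pts))
  gather <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1L] & iy >= 1 & iy <= d[2L] & iz >= 1 & iz <= d[3L]
    v <- numeric(length(ix))
    if (any(ok)) {
      lin <- (iz[ok] - 1) * d[1L] * d[2L] + (iy[ok] - 1) * d[1L] + ix[ok]
      v[ok] <- arr[lin]
    }
    v
  }
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
      (if (cz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- gather(x0[nz] + cx, y0[nz] + cy, z0[nz] + cz)
      out[nz] <- out[nz] + w[nz] * v
    }
  }
  out
}

# nearest-neighbour sampling; returns NA for out-of-grid points
.sample_nearest <- function(arr, pts) {
  d <- dim(arr)
  ix <- round(pts[, 1L]); iy <- round(pts[, 2L]); iz <- round(pts[, 3L])
  ok <- ix >= 1 & ix <= d[1L] & iy >= 1 & iy <= d[2L] & iz >= 1 & iz <= d[3L]
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    lin <- (iz[ok] - 1) * d[1L] * d[2L] + (iy[ok] - 1) * d[1L] + ix[ok]
    out[ok] <- arr[lin]
  }
  out
}
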