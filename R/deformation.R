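#' Spatial transforms between template and native space
#'
#' Transforms are represented as \code{deformation_field} objects mapping
#' template world coordinates (mm) to native world coordinates. Three
#' representations are supported: a 4x4 affine matrix, an affine composed
#' with a smooth parametric sinusoidal displacement, and a dense per-voxel
#' displacement field sampled on the template grid. Every representation
#' provides both the forward map and its inverse; the parametric and dense
#' inverses are computed by damped fixed-point iteration, which converges
#' because construction bounds the displacement amplitude so the map stays
#' injective.
#'
#' @name deformation_field
NULL

.new_deformation <- function(type, params, direction = "template_to_native") {
  structure(list(type = type, params = params, direction = direction,
                 inverted = FALSE),
            class = "deformation_field")
}

#' Affine transform
#'
#' @param matrix a 4x4 affine matrix acting on homogeneous world
#'   coordinates (mm), mapping template to native space.
#' @return a \code{deformation_field}.
#' @export
deformation_affine <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L)) || any(!is.finite(matrix)))
    stop("`matrix` must be a finite 4x4 affine matrix", call. = FALSE)
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine matrix is singular and cannot be inverted", call. = FALSE)
  .new_deformation("affine", list(A = matrix, Ainv = solve(matrix)))
}

#' Translation transform
#' @param shift_mm translation in mm (template to native).
#' @return a \code{deformation_field}.
#' @export
deformation_translation <- function(shift_mm) {
  shift_mm <- as.numeric(shift_mm)
  stopifnot(length(shift_mm) == 3L)
  A <- diag(4)
  A[1:3, 4] <- shift_mm
  deformation_affine(A)
}

#' Affine plus sinusoidal displacement
#'
#' The map is \code{phi(x) = A (x + u(x))} where the displacement
#' \code{u} is a divergence-free sinusoid: each component oscillates along
#' a different axis (\code{u_x} along y, \code{u_y} along z, \code{u_z}
#' along x). Being divergence-free, \code{u} preserves continuum volume,
#' so volume change is carried entirely by the affine part. Injectivity
#' requires \code{amplitude < wavelength / (2 * pi)}; violating this is an
#' error.
#'
#' @param affine 4x4 affine applied after the displacement.
#' @param amplitude displacement amplitude in mm (scalar or length-3).
#' @param wavelength spatial wavelength of the sinusoid in mm.
#' @param phase phase offsets (radians, length 3).
#' @return a \code{deformation_field}.
#' @export
deformation_sinusoidal <- function(affine = diag(4), amplitude = 0.5,
                                   wavelength = 16, phase = c(0, 0, 0)) {
  amplitude <- rep_len(as.numeric(amplitude), 3L)
  if (any(amplitude < 0) || wavelength <= 0)
    stop("amplitude must be >= 0 and wavelength > 0", call. = FALSE)
  if (max(amplitude) >= wavelength / (2 * pi))
    stop("requested displacement is not invertible: amplitude ",
         max(amplitude), " mm >= wavelength/(2*pi) = ",
         signif(wavelength / (2 * pi), 4), " mm", call. = FALSE)
  aff <- deformation_affine(affine)
  .new_deformation("sinusoidal",
                   list(A = aff$params$A, Ainv = aff$params$Ainv,
                        amplitude = amplitude, wavelength = wavelength,
                        phase = rep_len(as.numeric(phase), 3L)))
}

#' Dense displacement field
#'
#' @param displacement 4-D array \code{[nx, ny, nz, 3]} of world-space
#'   displacement vectors (mm) sampled at template grid voxel centres;
#'   the map is \code{phi(x) = x + u(x)} with \code{u} interpolated
#'   trilinearly (zero outside the grid).
#' @param spacing template grid spacing in mm.
#' @return a \code{deformation_field}.
#' @export
deformation_dense <- function(displacement, spacing) {
  if (!is.array(displacement) || length(dim(displacement)) != 4L ||
      dim(displacement)[4L] != 3L)
    stop("`displacement` must be an [nx, ny, nz, 3] array", call. = FALSE)
  spacing <- .check_positive_triple(spacing, "spacing")
  if (max(abs(displacement)) >= min(spacing) / 2)
    stop("requested displacement is not invertible: max |u| = ",
         signif(max(abs(displacement)), 4), " mm >= half the control grid",
         " spacing (", signif(min(spacing) / 2, 4), " mm)", call. = FALSE)
  .new_deformation("dense", list(u = displacement, spacing = spacing))
}

#' Reverse the direction of a deformation
#'
#' Returns a transform whose forward map is the inverse of \code{def}
#' (e.g. native-to-template from a template-to-native field).
#' @param def a \code{deformation_field}.
#' @return a \code{deformation_field} with direction reversed.
#' @export
invert_deformation <- function(def) {
  stopifnot(inherits(def, "deformation_field"))
  def$inverted <- !def$inverted
  def$direction <- if (identical(def$direction, "template_to_native"))
    "native_to_template" else "template_to_native"
  def
}

# displacement u evaluated at world points (n x 3), for parametric/dense types
.def_displacement <- function(def, pts) {
  p <- def$params
  if (def$type == "sinusoidal") {
    w <- 2 * pi / p$wavelength
    cbind(p$amplitude[1L] * sin(w * pts[, 2L] + p$phase[1L]),
          p$amplitude[2L] * sin(w * pts[, 3L] + p$phase[2L]),
          p$amplitude[3L] * sin(w * pts[, 1L] + p$phase[3L]))
  } else {
    vox <- .world_to_voxel(pts, p$spacing)
    cbind(.sample_trilinear(p$u[, , , 1L], vox),
          .sample_trilinear(p$u[, , , 2L], vox),
          .sample_trilinear(p$u[, , , 3L], vox))
  }
}

.def_forward_raw <- function(def, pts) {
  p <- def$params
  switch(def$type,
         affine = {
           t(p$A[1:3, 1:3] %*% t(pts)) +
             matrix(p$A[1:3, 4], nrow(pts), 3L, byrow = TRUE)
         },
         sinusoidal = {
           y <- pts + .def_displacement(def, pts)
           t(p$A[1:3, 1:3] %*% t(y)) +
             matrix(p$A[1:3, 4], nrow(pts), 3L, byrow = TRUE)
         },
         dense = pts + .def_displacement(def, pts))
}

.def_inverse_raw <- function(def, pts, tol = 1e-10, max_iter = 100L) {
  p <- def$params
  if (def$type == "affine") {
    return(t(p$Ainv[1:3, 1:3] %*% t(pts)) +
             matrix(p$Ainv[1:3, 4], nrow(pts), 3L, byrow = TRUE))
  }
  if (def$type == "sinusoidal") {
    z <- t(p$Ainv[1:3, 1:3] %*% t(pts)) +
      matrix(p$Ainv[1:3, 4], nrow(pts), 3L, byrow = TRUE)
  } else {
    z <- pts
  }
  # solve x = z - u(x) by fixed-point iteration; contraction guaranteed by
  # the amplitude bound enforced at construction
  x <- z
  for (i in seq_len(max_iter)) {
    xn <- z - .def_displacement(def, x)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  x
}

#' Apply a deformation to world points
#'
#' @param def a \code{deformation_field}.
#' @param pts n x 3 matrix of world coordinates (mm) in the transform's
#'   source space.
#' @return n x 3 matrix of mapped coordinates.
#' @export
deform_points <- function(def, pts) {
  stopifnot(inherits(def, "deformation_field"))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  if (def$inverted) .def_inverse_raw(def, pts) else .def_forward_raw(def, pts)
}

#' Apply the inverse of a deformation to world points
#'
#' @inheritParams deform_points
#' @return n x 3 matrix of pre-image coordinates.
#' @export
deform_points_inverse <- function(def, pts) {
  stopifnot(inherits(def, "deformation_field"))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  if (def$inverted) .def_forward_raw(def, pts) else .def_inverse_raw(def, pts)
}

#' Read / write an affine transform as a 4x4 text matrix
#'
#' @param path path to a whitespace-delimited text file holding 4 rows of
#'   4 numbers.
#' @return \code{read_affine_transform}: a \code{deformation_field}.
#' @export
read_affine_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!all(dim(m) == c(4L, 4L)))
    stop("affine transform file must contain a 4x4 matrix: ", path,
         call. = FALSE)
  deformation_affine(unname(m))
}

#' @rdname read_affine_transform
#' @param def an affine \code{deformation_field}.
#' @export
write_affine_transform <- function(def, path) {
  stopifnot(inherits(def, "deformation_field"), def$type == "affine")
  utils::write.table(format(def$params$A, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dense displacement field as a vector-valued NIfTI
#'
#' @param path path to a 4-D NIfTI whose fourth dimension holds the x/y/z
#'   displacement components in mm.
#' @param spacing template grid spacing (mm); taken from the NIfTI header
#'   when reading.
#' @return \code{read_displacement_field}: a \code{deformation_field}.
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 5L) arr <- arr[, , , 1L, , drop = TRUE]
  if (length(dim(arr)) != 4L || dim(arr)[4L] != 3L)
    stop("displacement field must be [nx, ny, nz, 3]: ", path, call. = FALSE)
  deformation_dense(arr, spacing = RNifti::pixdim(img)[seq_len(3L)])
}

#' @rdname read_displacement_field
#' @param def a dense \code{deformation_field}.
#' @export
write_displacement_field <- function(def, path) {
  stopifnot(inherits(def, "deformation_field"), def$type == "dense")
  img <- RNifti::asNifti(def$params$u)
  RNifti::pixdim(img) <- c(def$params$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
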