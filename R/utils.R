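# internal helpers shared across modules

# linearized voxel index with x fastest, then y, then z (1-based)
.linear_index <- function(vox, dim) {
  (vox[, 3L] - 1L) * dim[1L] * dim[2L] + (vox[, 2L] - 1L) * dim[1L] + vox[, 1L]
}

.from_linear <- function(lin, dim) {
  lin0 <- lin - 1L
  x <- lin0 %% dim[1L]
  y <- (lin0 %/% dim[1L]) %% dim[2L]
  z <- lin0 %/% (dim[1L] * dim[2L])
  cbind(x + 1L, y + 1L, z + 1L)
}

.check_positive_triple <- function(x, what) {
  if (length(x) != 3L || any(!is.finite(x)) || any(x <= 0))
    stop("`", what, "` must be three positive finite values", call. = FALSE)
  as.numeric(x)
}

# neighbourhood offsets for the 6/18/26 lattice connectivities
.connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be one of 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = manh == 1,
                 "18" = manh >= 1 & manh <= 2,
                 "26" = manh >= 1)
  unname(off[keep, , drop = FALSE])
}

# deterministic per-subject stream seed derived from a design seed
.subject_seed <- function(seed, subject_index, stage = 0L) {
  base <- (as.double(seed) * 7919 + as.double(subject_index) * 104729 +
             as.double(stage) * 15485863) %% 2147483629
  as.integer(base) + 1L
}
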