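# compact phantom designs used across tests (small grids keep the suite
# fast; the template-box geometry itself is never shrunk)

small_lc_design <- function(n_per_group = c(Control = 2), noise_sigma = 0,
                            cluster = 20L, seed = 1, ...) {
  phantom_design(n_per_group = n_per_group, noise_sigma = noise_sigma,
                 lc_cluster_voxels = cluster,
                 tse_grid = c(112, 112, 20),
                 lc_missing_by_group = 0, seed = seed, ...)
}

# a coarse-voxel design for simulation studies (0.8 mm in-plane keeps the
# box geometry intact while shrinking the slab to ~18k voxels)
coarse_lc_design <- function(n_per_group, lc_contrast_by_group,
                             seed = 1, ...) {
  phantom_design(n_per_group = n_per_group,
                 lc_contrast_by_group = lc_contrast_by_group,
                 tse_voxel = c(0.8, 0.8, 3), tse_grid = c(52, 52, 10),
                 box_geometry = list(fov_mm = c(38.4, 38.4, 24)),
                 lc_missing_by_group = 0, distractors = 0L,
                 seed = seed, ...)
}

# measure LC-I on a phantom subject using its construction boxes
measure_lc <- function(subject, ...) {
  compute_lc_intensity(subject$tse_image, subject$native_boxes, ...)
}
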