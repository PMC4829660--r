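# Shared fixtures: small, fast synthetic worlds used across test files.

# A small nucleus whose foci are separable by every modality: the pairwise
# exclusion zone is 4x the confocal lateral FWHM laterally and matches the
# ~3x worse axial resolution axially.
small_separated_world <- function(n_foci = 15, seed = 1) {
  generate_nucleus_stack(
    n_foci, modality_profile("sim"),
    nucleus = list(semi_axes_nm = c(3500, 3500, 800)),
    min_sep_nm = 1040, min_sep_axial_nm = 2830, seed = seed)
}

# Clustered world with a known merge factor: clusters of `cluster_size` foci
# on rings small enough to fuse at conventional resolution but resolvable by
# the sim profile.
clustered_world <- function(n_foci = 100, cluster_size = 5, seed = 1,
                            semi_axes = c(5000, 5000, 1200)) {
  generate_nucleus_stack(
    n_foci, modality_profile("sim"),
    clustering = list(enabled = TRUE, mean_size = cluster_size,
                      radius_nm = 220, layout = "ring",
                      parent_min_sep_nm = 1400),
    nucleus = list(semi_axes_nm = semi_axes), seed = seed)
}

# Deterministic single-slice stack from a matrix.
slice_stack <- function(m, vz = 125) {
  voxel_stack(array(m, dim = c(nrow(m), ncol(m), 1)), 40, vz, "test")
}

# An isotropic 2D Gaussian blob on a ny x nx grid.
gauss_blob <- function(ny, nx, cy, cx, sigma, amp = 1) {
  outer(seq_len(ny), seq_len(nx), function(i, j)
    amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
}
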