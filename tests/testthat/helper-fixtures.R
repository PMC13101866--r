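# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# solid sphere / ellipsoid rendered on a voxel grid (amplitude on background)
make_sphere_stack <- function(dim3 = c(41, 41, 41), spacing = c(1, 1, 1),
                              center = NULL, radius = 6, amplitude = 1,
                              background = 0) {
  if (is.null(center)) center <- dim3 * spacing / 2
  g <- expand.grid(z = seq_len(dim3[1]), y = seq_len(dim3[2]), x = seq_len(dim3[3]))
  pos <- cbind((g$z - 0.5) * spacing[1], (g$y - 0.5) * spacing[2],
               (g$x - 0.5) * spacing[3])
  rr <- sqrt(rowSums(sweep(pos, 2, center)^2))
  arr <- array(background + amplitude * (rr <= radius), dim3)
  image_stack(arr, spacing)
}

# analytic voxelized sphere count (same voxel-centre convention)
voxelized_sphere_count <- function(dim3, spacing, center, radius) {
  s <- make_sphere_stack(dim3, spacing, center, radius)
  sum(s > 0)
}

# small noise-free, PSF-free tube configs for geometry tests
quiet_config <- function(...) {
  synthetic_config(..., n_nuclei_by_compartment = rep(0L, 5),
                   psf_sigma = c(0, 0, 0),
                   noise = list(gaussian_sd = 0, poisson_scale = 0))
}

# a small default-style heart shared by several files (cheap to rebuild)
small_heart <- function(seed = 7, ...) {
  synthesize_heart(synthetic_config(
    grid_shape = c(48, 100, 150),
    centerline_params = list(radius = 50, turn_fraction = 0.5),
    tube_radius_by_compartment = c(12, 16, 8, 18, 12),
    n_nuclei_by_compartment = c(3, 7, 5, 8, 4),
    seed = seed, ...))
}

# greedy truth-to-detection volume matching used in recovery tests
match_volumes <- function(truth_nuclei, measured) {
  tc <- as.matrix(truth_nuclei[, c("z_um", "y_um", "x_um")])
  mc <- as.matrix(measured[, c("z_um", "y_um", "x_um")])
  j <- apply(tc, 1, function(p) which.min(colSums((t(mc) - p)^2)))
  data.frame(true_vol = truth_nuclei$volume_um3,
             meas_vol = measured$volume_um3[j],
             dist = sqrt(colSums((t(mc[j, , drop = FALSE]) - t(tc))^2)))
}
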