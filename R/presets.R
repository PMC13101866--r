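#' Benchmark cohort configuration for AVC volume-effect studies
#'
#' A straight heart tube whose AVC hosts 90 wall-resident nuclei (plus a few
#' flanking atrial/ventricular nuclei), mirroring the pooled per-group
#' nucleus counts of typical embryo cohorts (~90-110 AVC nuclei pooled over
#' 4-12 embryos). Condition contrasts are programmed through
#' `nucleus_volume_factor` (e.g. 1.25 for a 25% larger mutant AVC nucleus
#' volume). Voxels are anisotropic (2 x 1 x 1 um), exercising the
#' anisotropy-aware segmentation path.
#'
#' @param nucleus_volume_factor programmed volume effect (1 = control)
#' @param group condition tag
#' @param seed generator seed
#' @param n_avc number of AVC nuclei (default 90)
#' @return a [synthetic_config()]
#' @export
avc_cohort_config <- function(nucleus_volume_factor = 1, group = "control",
                              seed = 1L, n_avc = 90L) {
  synthetic_config(
    grid_shape = c(36, 72, 360), spacing = c(2, 1, 1),
    centerline_kind = "straight", centerline_params = list(length = 300),
    compartment_fractions = c(0.04, 0.08, 0.75, 0.08, 0.05),
    tube_radius_by_compartment = c(16, 16, 14, 16, 16),
    n_nuclei_by_compartment = c(0L, 4L, as.integer(n_avc), 4L, 0L),
    nucleus_volume_factor = nucleus_volume_factor,
    group = group, seed = seed)
}
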