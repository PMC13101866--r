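---
title: "Quantifying heart-tube morphology and nucleus volumes in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heart-tube morphology and nucleus volumes in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

During zebrafish heart development, endocardial cells (EdCs) of the
atrioventricular canal (AVC) shrink as the heart loops, and this volume
change is commonly read out through nucleus volume as a proxy for cell
volume. Quantifying such phenotypes from live confocal stacks requires a
chain of image-analysis steps: segmenting nuclei in 3D and measuring their
volumes in physical units, deciding which anatomical compartment each
nucleus belongs to (pre-atrium, atrium, AVC, ventricle, postventricle),
measuring the shape of the endocardial lumen (AVC length and how strongly
the tube loops), and quantifying membrane-localized protein signal by
reading intensity profiles drawn perpendicular to the plasma membrane.

`hearttube` implements this chain as a reproducible, scriptable pipeline,
and pairs it with a synthetic heart-tube generator that produces images with
complete analytic ground truth. Every stage is therefore testable without
any acquired data: the generator states a world (tube geometry, nucleus
sizes, membrane contrasts, optics, noise), the pipeline measures it, and the
tests check that the programmed quantities are recovered.

# The synthetic heart tube

The generator (`synthetic_config()` / `synthesize_heart()`) renders:

* **A centerline** — straight, circular arc, helix, or spline — densely
  sampled (segment length at most half the smallest voxel edge) and placed
  in the grid with a safety margin of the maximum tube radius plus three PSF
  sigmas. Curve endpoints define the inflow/outflow points of the ground
  truth, and the analytic convolutedness is total arc length over endpoint
  separation.
* **A lumen**: voxels within a compartment-dependent radius of the
  centerline. The five compartments partition the lumen by arc-length
  fractions; the AVC is the narrowest compartment by default (10 um vs
  16-24 um), as in the embryonic heart. Ball-stamping along the polyline
  would leave spherical caps past the tube ends; these are cropped by
  half-space tests so the tube is open-ended and a straight tube's lumen
  matches the analytic cylinder volume within ~1%.
* **Nuclei**: ellipsoids with per-compartment mean semi-axes (default
  4.2 x 3.2 x 2.6 um, ~145 um^3, a realistic EdC nucleus volume) and
  Gaussian size jitter (sd 0.3 um), centred at 85% of the local tube radius
  to mimic wall-resident cells, oriented uniformly at random, placed by
  rejection sampling that forbids centre distances below the sum of the two
  maximal semi-axes. Condition effects scale volumes through
  `nucleus_volume_factor` (semi-axes by its cube root).
* **A membrane shell**: 1.5 um thick, centred on the lumen boundary, with
  per-compartment intensity; the default programs a 2x AVC enrichment over
  the atrium, the kind of contrast seen for membrane water channels at the
  AVC.
* **Golgi offsets** for polarity testing: 3 um offsets drawn from a
  von-Mises-Fisher-like scheme (`normalize(k * mu + u)`, `u` uniform on the
  sphere) around the local inflow-pointing tangent, with concentration 4 by
  default, so most cells are called inflow-polarized.
* **Optics and noise**: both channels are blurred by an anisotropic Gaussian
  PSF (default sigma 1.2 um axially, 0.6 um laterally, typical of a mid-NA
  confocal at ~1 um voxels) and corrupted by Poisson noise on photon counts
  followed by additive Gaussian read noise (sd 4 on a 120-photon nuclear
  amplitude). Both noise terms can be switched off independently, which the
  exact geometry tests rely on.

What the generator does **not** emulate: depth-dependent attenuation,
spherical aberration, beating-tissue motion, autofluorescent yolk, touching
nuclei in mitosis, or segmentation-confusing debris. A green test therefore
establishes that the measurement chain is unbiased under stated optics and
noise — not that any particular trained network would segment real embryos
correctly. This is deliberate: the package replaces the deep-learning
segmentation stages of typical pipelines with classical, parameter-explicit
methods at desk scale.

Determinism: `synthesize_heart()` seeds a local RNG stream from
`config$seed` and restores the caller's RNG state, so identical configs give
bit-identical volumes and two seeds differ only in their random draws.

# Nucleus segmentation and volume measurement

Detection uses the multiscale Laplacian of Gaussian. For each scale `sigma`
(in um) the image is convolved per axis with Gaussian kernels of
`sigma / spacing[axis]` voxels — anisotropy is handled in the kernels, not by
resampling, preserving the nuclear channel's native resolution. The response
is the negated physical-unit Laplacian scale-normalized by `sigma^2`
(gamma = 2), the standard choice that makes responses of blobs of different
sizes comparable; a solid sphere of radius r peaks at `sigma = r / sqrt(3)`,
which the tests verify by brute-force scans. Seeds are space-scale local
maxima above a threshold, pruned greedily (highest response first, ties by
voxel order) to a minimum separation.

Instances are grown by marker-controlled watershed (26-connectivity,
deterministic flooding order: cost, then insertion order) over the inverted
smoothed intensity — or the negated distance transform, selectable —
restricted to a foreground mask. The default mask threshold is Otsu's, but
Otsu alone is a poor volume estimator for PSF-blurred objects: the blurred
skirt of a ~3 um-semi-axis nucleus pushes the global threshold far into the
background and inflated volumes by ~50% in our phantoms. Each instance is
therefore tightened at `background + 0.4 * (instance peak - background)`,
keeping the seed's connected component. The 0.4 fraction was calibrated on
blurred-ellipsoid phantoms spanning the generator's nucleus size range
(half-maximum, the unbiased cut for a planar blurred edge, under-segments
small curved objects; 0.4 was stable at 2-3% median volume error across
smoothing sigmas 0.5-1 um). It is exposed as `refine_fraction` and can be
disabled.

Volumes are exact voxel counts times the voxel volume; centroids are means
of voxel centres. Coordinates follow one convention everywhere: axis order
(z, y, x), 0-based voxel index `v` centred at `(v + 0.5) * spacing` um.

# Compartments, normalization, polarity, statistics

Compartment assignment is geometric: a nucleus takes the compartment of its
nearest centerline arc-length position, and is `unassigned` beyond a 20 um
cutoff from the lumen surface. The original analyses assigned the "innermost
region of the AVC" manually; a geometric rule trades that judgement for
reproducibility.

Volume normalization divides by the mean of a reference subset (by default
the control group's AVC nuclei), following the "normalized to mean control
value" convention of the figures this mirrors; the reference's normalized
mean is exactly 1, and the operation is idempotent. Whether such studies
normalize to the pooled control mean or per-clutch means is usually
unstated; the pooled mean is implemented.

Polarity is classified from the angle between the nucleus-to-Golgi vector
and the inflow axis: `inflow` within a 60 degree cone, `outflow` within the
opposite cone, `unpolarized` between. The 60 degree default replaces a
visual criterion that was never quantified; it is configurable, and
percentages always sum to 100.

Group comparisons implement the tests named in the relevant figure legends:
Mann-Whitney (exact permutation null by full enumeration when both groups
have at most 8 observations — midranks make it tie-safe — and the
tie-corrected normal approximation with continuity correction otherwise),
the unpaired equal-variance t test, and Kruskal-Wallis. The exact and
approximate Mann-Whitney branches agree within 0.02 at n = 8 per group,
which the suite checks over 100 random datasets. Two-way ANOVA on polarity
percentages is deliberately delegated to standard routines and not
re-implemented.

# Lumen morphometry

All morphometry runs at 2 um isotropic resolution by default (nearest
neighbour for labels, trilinear for intensities), matching the preprocessing
convention of the segmentation models this emulates. Compartment interfaces
are sets of voxel-face midpoints under 6-adjacency — face adjacency gives a
well-defined oriented surface — and their centroids define: the inflow point
(pre-atrium|atrium), the outflow point (ventricle|postventricle), and the
AVC length (distance between the atrium|AVC and AVC|ventricle centroids).

The central line is the minimal-cost 26-connected voxel path from inflow to
outflow with per-voxel cost `1 / (1 + d)^2`, where `d` is the
distance-to-boundary in um; the inverse-square weighting pins the path to
the lumen's medial ridge. The polyline is anchored at the exact requested
endpoints (snapping otherwise loses up to a voxel per end), smoothed by a
moving average (window 5) with pinned endpoints to suppress the zigzag of
grid paths, and summed into a length. How published analyses derive their
central line is typically unstated; a distance-ridge shortest path was
chosen because it is deterministic and parameter-light.

Convolutedness (the looping ratio) is central-line length over straight
inflow-outflow distance, so larger values mean a more looped heart; the
ratio orientation was chosen so the statistic increases with looping, and
would need revisiting against raw data if the opposite convention were ever
established. Voxelization keeps measured values within ~1% of 1.0 for a
straight tube and within ~2% of the arc/chord closed forms for semicircular
and quarter-circle tubes, which the acceptance tests assert at the stated
5% tolerances.

# Membrane line profiles

Anchors are drawn on the membrane mask (in the pipeline: uniformly at random
per region; analyses of real data would place them per cell). The normal at
an anchor is estimated by a local planar fit — the smallest-eigenvalue
eigenvector of the covariance of membrane voxels within a 4 um window. An
earlier design used the gradient of the smoothed signed distance transform,
but that gradient vanishes exactly on the shell mid-surface where the
anchors sit, making directions ill-conditioned (spherical-shell normals were
off by up to 23 degrees); the planar fit meets the 2 degree (plane) and
5 degree (sphere) targets. Anchors far from the membrane or with degenerate
fits are rejected with a warning, and the pipeline oversamples anchors to
compensate.

Profiles are sampled by trilinear interpolation from -3 to +3 um along the
normal in 0.25 um steps (defaults; the manual procedures this mirrors used
5-12 lines per cell of unstated length), in full 3D by default with a
single-z-plane mode for fidelity to the original 2D procedure. The
statistic per line is its maximum intensity — raw, not smoothed; whether the
original measurements smoothed first is unstated, and the maximum of a
trilinear profile is insensitive to step size below the voxel scale. An
optional constant background offset (`background = "median"`, the image
median) can be subtracted first: when ratios of region means are the
quantity of interest, a constant camera/autofluorescence pedestal dilutes
the contrast (a programmed 2x membrane enrichment reads as ~1.8x with the
default 5-photon pedestal left in), and a constant offset is the only form
of background correction in scope. The
per-line maxima are the units of downstream statistics, matching the
per-ROI analyses. A separate maximum-projection readout (`z`-MIP, then max
within a 2D ROI) covers RNAscope-style quantification, and
`normalize_to_reference()` implements the "normalized to mean AVC value"
convention.

# Pipeline and reproducibility

`run_pipeline()` executes generator, segmentation, assignment, morphometry,
profiles and comparison per heart, one directory per heart with fixed file
names, and pools per-group statistics — mirroring the per-embryo-then-pooled
structure of the original analyses. Each heart's seed is derived as
`seed + 1000 * group_index + heart_index` and logged in the report, so any
heart can be replayed in isolation; a failure in one heart (e.g. an
overcrowded placement) is recorded and does not abort the batch. The report
embeds an MD5 hash of the scientific configuration (output paths excluded),
and identical config + seed reproduce reports and TIFFs bit-identically.

Images travel as multi-page uncompressed TIFF (32-bit float intensities,
32-bit integer labels) with a JSON sidecar carrying voxel spacing; the
reader/writer implements only this baseline subset and is cross-validated
against an external TIFF implementation in the tests. Configuration files
are JSON.

# Numerical choices and known limitations

* Discrete LoG kernels are sampled analytically and corrected to zero
  response on constants; on small grids the optimum scale of large spheres
  can shift by one scan step, which the tests allow.
* The Felzenszwalb distance transform is exact under anisotropic spacing;
  watershed and Dijkstra tie-breaks are deterministic by insertion order.
* Moving-average smoothing of the central line slightly cuts corners on
  tightly curved tubes; at 2 um voxels the net length bias stays within the
  stated tolerances. Sub-voxel accuracy would need spline re-fitting, which
  is out of scope.
* The per-instance refinement fraction (0.4) is a phantom-calibrated
  constant, not a universal optimum; strongly non-Gaussian PSFs or
  heavy-tailed noise would warrant re-calibration.
* Compartment assignment needs a centerline; for real data this comes from
  the morphometry stage, for synthetic data from ground truth. Nuclei of
  real, convoluted hearts that sit near two limbs of the loop could be
  assigned to the geometrically nearest limb; the 20 um surface cutoff
  bounds but does not eliminate this.
* Statistics pool nuclei/ROIs across hearts, as the original analyses did;
  no per-embryo mixed-effects modelling is attempted.
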