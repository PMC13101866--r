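# hearttube

3D quantification of the embryonic zebrafish heart tube from multi-channel
fluorescence stacks — nucleus instance segmentation and volume measurement,
anatomical compartment assignment, lumen morphometry, membrane line-profile
intensity readout, and group statistics — plus a synthetic heart-tube
generator with complete analytic ground truth, so the entire measurement
chain is testable without any acquired data.

Written for developmental biologists and image analysts who quantify
looping-stage hearts: endocardial (EdC) nucleus volume as a proxy for cell
volume, the length of the atrioventricular canal (AVC), how strongly the
tube loops, and the enrichment of membrane proteins at the AVC.

## What it computes

**Nucleus segmentation.** Seeds come from a multiscale, scale-normalized
Laplacian of Gaussian: for scale $\sigma$ (µm), the response is

$$R_\sigma(x) = -\sigma^2 \, \nabla^2 (G_\sigma * I)(x),$$

with per-axis voxel sigmas $\sigma / \mathrm{spacing}$ (anisotropy-aware);
bright blobs of radius $r$ peak at $\sigma = r/\sqrt{3}$. Space–scale local
maxima above a threshold are pruned to a minimum separation, instances grow
by marker-controlled watershed on the inverted smoothed intensity, and each
instance is tightened at a phantom-calibrated fraction (0.4) of its
peak-over-background. Volume = voxel count × voxel volume, in µm³.

**Morphometry.** On compartment labels (pre-atrium = 1, atrium = 2, AVC = 3,
ventricle = 4, postventricle = 5), resampled to 2 µm isotropic: interface
centroids under 6-adjacency, AVC length = ‖c(atrium|AVC) − c(AVC|ventricle)‖,
inflow/outflow points from the outer interfaces, the central line as the
minimal-cost medial path (cost $1/(1+d)^2$, $d$ = distance to boundary), and

$$\mathrm{convolutedness} = \frac{\text{central-line length}}{\text{straight inflow–outflow distance}} \ge 1,$$

so larger = more looped.

**Membrane profiles.** Lines perpendicular to the membrane (normals from a
local planar fit of the membrane mask), sampled trilinearly over ±3 µm in
0.25 µm steps; the statistic per line is its **maximum** intensity, and
region means are compared after normalizing to a reference mean (e.g.
"normalized to mean AVC value").

**Statistics.** Mann-Whitney (exact enumeration for n ≤ 8 per group,
tie-corrected normal approximation otherwise), unpaired equal-variance
t test, Kruskal-Wallis.

## Worked example

```r
library(hearttube)

# a realistic ~48 hpf heart: 220 um semicircular tube, 70 nuclei,
# AVC narrowest, 2x AVC membrane enrichment, PSF + Poisson/Gaussian noise
heart <- synthesize_heart(synthetic_config(seed = 1))

seg <- segment_heart_nuclei(heart$nuclear)
nrow(seg$nuclei)
#> [1] 70

f1 <- detection_f1(heart$truth$nuclei[, c("z_um", "y_um", "x_um")],
                   seg$nuclei[, c("z_um", "y_um", "x_um")], match_radius = 3.3)
f1$f1
#> [1] 1

m <- heart_morphometry(heart$compartments)
m
#> <morphometry_result> AVC length 29.08 um, central line 155.97 um, straight 124.83 um, convolutedness 1.249
```

The measured AVC length (29.1 µm) matches the generator's analytic
interface chord (30.5 µm) to within a voxel and a half at the 2 µm working
resolution, and the convolutedness 1.25 is the arc/chord ratio of the
portion of the semicircular tube between the inflow and outflow interfaces
(analytic value 1.23). A two-group volume study:

```r
ctrl <- synthesize_heart(avc_cohort_config(1.00, "control", seed = 11))
mut  <- synthesize_heart(avc_cohort_config(1.25, "mutant",  seed = 12))  # +25% AVC volumes
pool <- rbind(
  within(assign_compartment(segment_heart_nuclei(ctrl$nuclear)$nuclei, ctrl$truth,
         tube_radius = ctrl$config$tube_radius_by_compartment), group <- "control"),
  within(assign_compartment(segment_heart_nuclei(mut$nuclear)$nuclei, mut$truth,
         tube_radius = mut$config$tube_radius_by_compartment), group <- "mutant"))
avc <- normalize_volumes(pool[pool$compartment == "AVC", ], "control", "AVC")
tapply(avc$volume_norm, avc$group, mean)
#>  control   mutant
#> 1.000000 1.203106
run_group_test(split(avc$volume_um3, avc$group), "mann_whitney")
#> <group_comparison> mann_whitney: statistic 1740, p = 3.819e-11 (n = 90, 90; ...)
```

The programmed 1.25× AVC volume effect is recovered as a 1.20× measured
ratio of group means with p ≪ 0.01 — the direction and magnitude of a
typical enlarged-AVC-nucleus phenotype.

## Command line

```sh
Rscript inst/cli/hearttube.R synthesize --config cfg.json --seed 1 --outdir heart1
Rscript inst/cli/hearttube.R segment-nuclei --image heart1/nuclear.tif --out seg1
Rscript inst/cli/hearttube.R morphometry --labels heart1/compartments.tif --out morpho.json
Rscript inst/cli/hearttube.R profiles --image heart1/membrane.tif --membrane heart1/membrane_regions.tif --n-lines 8 --out prof1
Rscript inst/cli/hearttube.R compare --nuclei a.csv,b.csv --test mann_whitney --reference control:AVC --out cmp.json
Rscript inst/cli/hearttube.R run --config run.json --outdir results
```

Images are multi-page uncompressed TIFF with a JSON sidecar carrying voxel
spacing (µm, axis order z,y,x); tables are CSV; configs and reports are
JSON.

## Conventions

Axis order is (z, y, x) everywhere; spacings and all physical quantities
are µm; voxel indices are 0-based with centres at `(index + 0.5) * spacing`;
compartment codes are 1–5 in the order pre-atrium, atrium, AVC, ventricle,
postventricle. See the methods vignette
(`vignettes/hearttube-methods.Rmd`) for the model, parameter defaults and
their rationale, and known limitations.
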