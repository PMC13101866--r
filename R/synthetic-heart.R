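#' Configuration for the synthetic heart-tube generator
#'
#' Describes a curved, five-compartment endocardial tube (pre-atrium, atrium,
#' AVC, ventricle, postventricle) with wall-resident ellipsoidal nuclei, a
#' thin membrane shell, Gaussian PSF blur and Poisson+Gaussian noise. The
#' defaults emulate a ~48 hpf zebrafish heart tube imaged at 1 um voxels:
#' a 220 um arc-shaped tube, an AVC that is the narrowest compartment, ~70
#' nuclei of ~145 um^3, and a 2x AVC membrane enrichment.
#'
#' @param grid_shape voxels per axis (z, y, x)
#' @param spacing um per voxel edge (z, y, x)
#' @param centerline_kind one of "straight", "arc", "helix", "spline"
#' @param centerline_params curve parameters: `length` (straight);
#'   `radius`, `turn_fraction` (arc; 0.5 = semicircle); `radius`, `pitch`,
#'   `t_max` (helix `x = R cos t, y = R sin t, z = pitch*t`); `points`
#'   (spline control points, n x 3 um)
#' @param compartment_fractions 5 positive arc-length fractions summing to 1
#'   (pre-atrium, atrium, AVC, ventricle, postventricle)
#' @param tube_radius_by_compartment lumen radius in um per compartment;
#'   default keeps the AVC narrowest
#' @param n_nuclei_by_compartment nucleus counts per compartment
#' @param nucleus_axes_mean mean ellipsoid semi-axes in um; either length 3
#'   (shared) or a 5 x 3 matrix (per compartment)
#' @param nucleus_axes_sd standard deviation of each semi-axis in um
#' @param nucleus_volume_factor condition effect: nucleus volumes are scaled
#'   by this factor (semi-axes by its cube root); 1 = control
#' @param wall_fraction nucleus centres sit at this fraction of the local
#'   tube radius
#' @param membrane_intensity_by_compartment shell intensity (photons/voxel)
#'   per compartment
#' @param nuclear_intensity nucleus intensity (photons/voxel)
#' @param background baseline intensity (photons/voxel)
#' @param membrane_thickness shell thickness in um before blurring
#' @param psf_sigma Gaussian PSF sigma in um per axis (z, y, x)
#' @param noise list with `gaussian_sd` (additive, intensity units) and
#'   `poisson_scale` (photon scaling; 0 disables shot noise)
#' @param golgi_distance nucleus-to-Golgi offset length in um
#' @param golgi_concentration concentration of Golgi offsets around the
#'   inflow-pointing tube tangent (larger = more polarized)
#' @param group condition tag attached to generated nuclei
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output
#' @return a validated `synthetic_config` object
#' @export
synthetic_config <- function(grid_shape = c(64, 132, 200),
                             spacing = c(1, 1, 1),
                             centerline_kind = "arc",
                             centerline_params = NULL,
                             compartment_fractions = c(0.12, 0.26, 0.14, 0.30, 0.18),
                             tube_radius_by_compartment = c(16, 22, 10, 24, 16),
                             n_nuclei_by_compartment = c(8, 18, 12, 22, 10),
                             nucleus_axes_mean = c(4.2, 3.2, 2.6),
                             nucleus_axes_sd = 0.3,
                             nucleus_volume_factor = 1,
                             wall_fraction = 0.85,
                             membrane_intensity_by_compartment = c(80, 80, 160, 80, 80),
                             nuclear_intensity = 120,
                             background = 5,
                             membrane_thickness = 1.5,
                             psf_sigma = c(1.2, 0.6, 0.6),
                             noise = list(gaussian_sd = 4, poisson_scale = 1),
                             golgi_distance = 3,
                             golgi_concentration = 4,
                             group = "control",
                             seed = 1L) {
  if (is.null(centerline_params)) {
    centerline_params <- switch(centerline_kind,
      straight = list(length = 220),
      arc = list(radius = 70, turn_fraction = 0.5),
      helix = list(radius = 40, pitch = 8, t_max = 3 * pi),
      spline = list(points = cbind(c(0, 0, 0, 0), c(0, 30, -10, 20),
                                   c(0, 60, 120, 180))),
      list())
  }
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    centerline_kind = centerline_kind, centerline_params = centerline_params,
    compartment_fractions = as.numeric(compartment_fractions),
    tube_radius_by_compartment = as.numeric(tube_radius_by_compartment),
    n_nuclei_by_compartment = as.integer(n_nuclei_by_compartment),
    nucleus_axes_mean = nucleus_axes_mean,
    nucleus_axes_sd = as.numeric(nucleus_axes_sd),
    nucleus_volume_factor = as.numeric(nucleus_volume_factor),
    wall_fraction = as.numeric(wall_fraction),
    membrane_intensity_by_compartment = as.numeric(membrane_intensity_by_compartment),
    nuclear_intensity = as.numeric(nuclear_intensity),
    background = as.numeric(background),
    membrane_thickness = as.numeric(membrane_thickness),
    psf_sigma = as.numeric(psf_sigma), noise = noise,
    golgi_distance = as.numeric(golgi_distance),
    golgi_concentration = as.numeric(golgi_concentration),
    group = group, seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    add("grid_shape must be 3 axis sizes of at least 4 voxels")
  if (length(cfg$spacing) != 3L || any(cfg$spacing <= 0))
    add("spacing must be 3 strictly positive um values")
  if (!cfg$centerline_kind %in% c("straight", "arc", "helix", "spline"))
    add(sprintf("unsupported centerline_kind '%s' (straight, arc, helix, spline)",
                cfg$centerline_kind))
  f <- cfg$compartment_fractions
  if (length(f) != 5L || any(f <= 0) || abs(sum(f) - 1) > 1e-9)
    add("compartment_fractions must be 5 positive values summing to 1 (tol 1e-9)")
  if (length(cfg$tube_radius_by_compartment) != 5L ||
      any(cfg$tube_radius_by_compartment <= 0))
    add("tube_radius_by_compartment must be 5 strictly positive um radii")
  if (length(cfg$n_nuclei_by_compartment) != 5L ||
      any(cfg$n_nuclei_by_compartment < 0))
    add("n_nuclei_by_compartment must be 5 non-negative counts")
  am <- nucleus_axes_matrix(cfg)
  if (any(am <= 0)) add("nucleus_axes_mean must be strictly positive")
  if (any(cfg$nucleus_axes_sd < 0)) add("nucleus_axes_sd must be non-negative")
  if (cfg$nucleus_volume_factor <= 0) add("nucleus_volume_factor must be positive")
  if (cfg$wall_fraction < 0 || cfg$wall_fraction > 1)
    add("wall_fraction must lie in [0, 1]")
  if (length(cfg$membrane_intensity_by_compartment) != 5L ||
      any(cfg$membrane_intensity_by_compartment < 0))
    add("membrane_intensity_by_compartment must be 5 non-negative intensities")
  if (cfg$membrane_thickness <= 0) add("membrane_thickness must be positive")
  if (length(cfg$psf_sigma) != 3L || any(cfg$psf_sigma < 0))
    add("psf_sigma must be 3 non-negative um values")
  if (is.null(cfg$noise$gaussian_sd) || is.null(cfg$noise$poisson_scale) ||
      cfg$noise$gaussian_sd < 0 || cfg$noise$poisson_scale < 0)
    add("noise must provide non-negative gaussian_sd and poisson_scale")
  if (length(errs)) stop("invalid synthetic_config:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg
}

nucleus_axes_matrix <- function(cfg) {
  am <- cfg$nucleus_axes_mean
  if (is.matrix(am)) {
    if (!all(dim(am) == c(5L, 3L)))
      stop("nucleus_axes_mean matrix must be 5 compartments x 3 semi-axes")
    am
  } else {
    if (length(am) != 3L) stop("nucleus_axes_mean must have 3 semi-axes")
    matrix(rep(as.numeric(am), each = 5L), nrow = 5L)
  }
}

#' Build the tube centerline for a synthetic configuration
#'
#' Samples the configured curve densely (segment length at most half the
#' smallest voxel edge), recentres it in the grid, and checks that it stays
#' inside the grid with a margin of at least the maximum tube radius plus
#' three PSF sigmas.
#'
#' @param config a [synthetic_config()]
#' @return list with `points` (n x 3 um, z,y,x), monotonic cumulative
#'   `arclen` (um), `inflow` and `outflow` (curve endpoints, um), and `kind`
#' @export
make_centerline <- function(config) {
  p <- config$centerline_params
  t <- seq(0, 1, length.out = 4096L)
  pts <- switch(config$centerline_kind,
    straight = {
      if (is.null(p$length) || p$length <= 0) stop("straight centerline needs length > 0")
      cbind(0, 0, t * p$length)
    },
    arc = {
      if (is.null(p$radius) || is.null(p$turn_fraction) || p$radius <= 0 ||
          p$turn_fraction <= 0 || p$turn_fraction > 1)
        stop("arc centerline needs radius > 0 and turn_fraction in (0, 1]")
      th <- t * 2 * pi * p$turn_fraction
      cbind(0, p$radius * sin(th), p$radius * cos(th))
    },
    helix = {
      if (is.null(p$radius) || is.null(p$pitch) || is.null(p$t_max) ||
          p$radius <= 0 || p$t_max <= 0)
        stop("helix centerline needs radius > 0, pitch, t_max > 0")
      th <- t * p$t_max
      cbind(p$pitch * th, p$radius * sin(th), p$radius * cos(th))
    },
    spline = {
      cp <- p$points
      if (is.null(cp) || !is.matrix(cp) || ncol(cp) != 3L || nrow(cp) < 3L)
        stop("spline centerline needs an n x 3 matrix of at least 3 points")
      u <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
      u <- u / max(u)
      cbind(spline(u, cp[, 1], xout = t)$y,
            spline(u, cp[, 2], xout = t)$y,
            spline(u, cp[, 3], xout = t)$y)
    },
    stop("unsupported centerline_kind: ", config$centerline_kind))

  # resample uniformly by arc length at half the smallest voxel edge
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  step <- 0.5 * min(config$spacing)
  s_out <- seq(0, total, by = step)
  if (s_out[length(s_out)] < total) s_out <- c(s_out, total)
  pts <- cbind(approx(s, pts[, 1], xout = s_out)$y,
               approx(s, pts[, 2], xout = s_out)$y,
               approx(s, pts[, 3], xout = s_out)$y)
  colnames(pts) <- c("z", "y", "x")

  # recenter the curve's bounding box at the grid centre, then margin-check
  extent <- config$grid_shape * config$spacing
  mid <- (apply(pts, 2, min) + apply(pts, 2, max)) / 2
  pts <- sweep(pts, 2, extent / 2 - mid, `+`)
  margin <- max(config$tube_radius_by_compartment) + 3 * max(config$psf_sigma)
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  bad <- which(lo < 0 | hi > extent)
  if (length(bad))
    stop(sprintf(
      "centerline exits the grid on axis %s: needs margin %.1f um but grid extent is (%s) um",
      paste(c("z", "y", "x")[bad], collapse = ","), margin,
      paste(signif(extent, 4), collapse = ", ")))
  arclen <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, arclen = arclen,
       inflow = pts[1, ], outflow = pts[nrow(pts), ],
       kind = config$centerline_kind)
}

# parallel-transported orthonormal frames (tangent, normal, binormal) along
# a polyline; avoids the twisting of naive Frenet frames on straight spans
transport_frames <- function(pts) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[-(1:2), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
                pts[n, ] - pts[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nor <- matrix(0, n, 3)
  bin <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * tang[1, ]) * tang[1, ]
  nor[1, ] <- v / sqrt(sum(v^2))
  bin[1, ] <- cross3(tang[1, ], nor[1, ])
  for (i in 2:n) {
    v <- nor[i - 1, ] - sum(nor[i - 1, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- cross3(bin[i - 1, ], tang[i, ]) else v <- v / nv
    nor[i, ] <- v / sqrt(sum(v^2))
    bin[i, ] <- cross3(tang[i, ], nor[i, ])
  }
  list(tangent = tang, normal = nor, binormal = bin)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# uniformly random rotation matrix (rows = principal axes) from a quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Synthesize a multi-channel heart-tube image with full ground truth
#'
#' Renders the configured tube: lumen voxels within a compartment-dependent
#' radius of the centerline, compartments labelled 1-5 by arc-length
#' interval, non-overlapping ellipsoidal nuclei centred near the tube wall, a
#' thin membrane shell at the lumen boundary with compartment-dependent
#' intensity; both channels are blurred by a Gaussian PSF and corrupted by
#' Poisson then Gaussian noise. Fully reproducible under `config$seed`.
#'
#' @param config a [synthetic_config()]
#' @return a `synthetic_heart` list: `nuclear` and `membrane`
#'   ([image_stack()]s), `compartments`, `membrane_regions` and `nuclei_true`
#'   ([label_volume()]s), and `truth` (ground truth: centerline, compartment
#'   arc-length intervals, per-nucleus analytic geometry, Golgi offsets,
#'   inflow/outflow points, analytic AVC length and convolutedness)
#' @export
synthesize_heart <- function(config) {
  config <- validate_synthetic_config(config)
  with_local_seed(config$seed, {
    dim3 <- config$grid_shape
    sp <- config$spacing
    cl <- make_centerline(config)
    total <- cl$arclen[length(cl$arclen)]
    breaks <- cumsum(config$compartment_fractions) * total
    comp_of_s <- function(s) pmin(5L, findInterval(s, c(-Inf, breaks[1:4])))
    radius_pt <- config$tube_radius_by_compartment[comp_of_s(cl$arclen)]

    paint <- .paint_tube_cpp(dim3, sp, cl$points, cl$arclen, radius_pt,
                             config$membrane_thickness / 2 + max(sp))
    dist <- paint$dist
    rad_at <- paint$radius
    arc_at <- paint$arclen
    in_tube <- is.finite(dist)
    # crop the spherical caps the ball-stamping leaves past the tube ends, so
    # the lumen is an open-ended tube (flat end planes at inflow/outflow)
    sel <- which(in_tube)
    pos <- vox_to_um(lin_to_zyx0(sel, dim3), sp)
    n_cl <- nrow(cl$points)
    t_in <- cl$points[2, ] - cl$points[1, ]
    t_in <- t_in / sqrt(sum(t_in^2))
    t_out <- cl$points[n_cl, ] - cl$points[n_cl - 1, ]
    t_out <- t_out / sqrt(sum(t_out^2))
    beyond <- (sweep(pos, 2, cl$inflow) %*% t_in)[, 1] < 0 |
      (sweep(pos, 2, cl$outflow) %*% t_out)[, 1] > 0
    in_tube[sel[beyond]] <- FALSE
    lumen <- in_tube & dist <= rad_at
    shell <- in_tube & abs(dist - rad_at) <= config$membrane_thickness / 2

    comp_lab <- array(0L, dim3)
    comp_lab[lumen] <- comp_of_s(arc_at[lumen])
    shell_lab <- array(0L, dim3)
    shell_lab[shell] <- comp_of_s(arc_at[shell])

    nuc <- place_nuclei(config, cl, breaks, comp_of_s)
    nuclei_true <- .paint_ellipsoids_cpp(dim3, sp, nuc$centers, nuc$axes, nuc$rot)

    nuclear <- array(config$background, dim3)
    nuclear[nuclei_true > 0L] <- config$background + config$nuclear_intensity
    membrane <- array(config$background, dim3)
    membrane[shell] <- config$background +
      config$membrane_intensity_by_compartment[shell_lab[shell]]

    blur <- function(a) {
      if (all(config$psf_sigma <= 0)) return(a)
      .gaussian_blur3d_cpp(a, dim3, config$psf_sigma / sp)
    }
    corrupt <- function(a) {
      if (config$noise$poisson_scale > 0)
        a <- array(rpois(length(a), pmax(a, 0) * config$noise$poisson_scale) /
                     config$noise$poisson_scale, dim3)
      if (config$noise$gaussian_sd > 0)
        a <- a + array(rnorm(length(a), 0, config$noise$gaussian_sd), dim3)
      a
    }
    nuclear <- corrupt(blur(nuclear))
    membrane <- corrupt(blur(membrane))

    intervals <- data.frame(
      compartment = COMPARTMENTS, code = 1:5,
      arclen_lo = c(0, breaks[1:4]), arclen_hi = breaks)
    truth <- structure(list(
      centerline = cl$points, arclen = cl$arclen,
      compartment_intervals = intervals,
      nuclei = nuc$table, rotations = nuc$rot,
      golgi_offsets = nuc$golgi,
      inflow_point = cl$inflow, outflow_point = cl$outflow,
      analytic_avc_length = sqrt(sum((centerline_at(cl, breaks[2]) -
                                        centerline_at(cl, breaks[3]))^2)),
      analytic_centerline_length = total,
      analytic_convolutedness = total / sqrt(sum((cl$outflow - cl$inflow)^2))),
      class = "heart_ground_truth")

    structure(list(
      nuclear = image_stack(nuclear, sp, channel = "nuclear"),
      membrane = image_stack(membrane, sp, channel = "membrane"),
      compartments = label_volume(comp_lab, sp),
      membrane_regions = label_volume(shell_lab, sp),
      nuclei_true = label_volume(nuclei_true, sp),
      truth = truth, config = config), class = "synthetic_heart")
  })
}

# interpolate the centerline position at a given arc length
centerline_at <- function(cl, s) {
  c(approx(cl$arclen, cl$points[, 1], xout = s)$y,
    approx(cl$arclen, cl$points[, 2], xout = s)$y,
    approx(cl$arclen, cl$points[, 3], xout = s)$y)
}

# rejection-sample non-overlapping wall-resident nuclei per compartment
place_nuclei <- function(config, cl, breaks, comp_of_s) {
  frames <- transport_frames(cl$points)
  am <- nucleus_axes_matrix(config) * config$nucleus_volume_factor^(1 / 3)
  extent <- config$grid_shape * config$spacing
  lo_b <- c(0, breaks[1:4])
  centers <- NULL; axes <- NULL; rots <- NULL
  comp_out <- integer(0); svals <- numeric(0)
  maxsum <- numeric(0)
  for (comp in 1:5) {
    want <- config$n_nuclei_by_compartment[comp]
    if (want == 0L) next
    pad <- max(am[comp, ]) + config$nucleus_axes_sd
    lo <- lo_b[comp] + pad
    hi <- breaks[comp] - pad
    if (hi <= lo) stop(sprintf(
      "compartment %s is too short (%.1f um) to host nuclei of semi-axis %.1f um",
      COMPARTMENTS[comp], breaks[comp] - lo_b[comp], pad))
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * want
    while (placed < want) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "failed to place %d nuclei in compartment %s after %d attempts (overcrowded; placed %d)",
          want, COMPARTMENTS[comp], max_attempts, placed))
      s <- runif(1, lo, hi)
      i <- findInterval(s, cl$arclen)
      phi <- runif(1, 0, 2 * pi)
      a3 <- pmax(rnorm(3, am[comp, ], config$nucleus_axes_sd), 0.5)
      a3 <- sort(a3, decreasing = TRUE)
      rho <- config$wall_fraction * config$tube_radius_by_compartment[comp]
      ctr <- cl$points[i, ] +
        rho * (cos(phi) * frames$normal[i, ] + sin(phi) * frames$binormal[i, ])
      marg <- max(a3) + 1
      if (any(ctr < marg) || any(ctr > extent - marg)) next
      rot <- random_rotation()
      ok <- TRUE
      if (!is.null(centers)) {
        dd <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
        if (any(dd <= maxsum + max(a3))) ok <- FALSE
      }
      if (!ok) next
      centers <- rbind(centers, ctr)
      axes <- rbind(axes, a3)
      rots <- rbind(rots, as.vector(t(rot)))
      comp_out <- c(comp_out, comp)
      svals <- c(svals, s)
      maxsum <- c(maxsum, max(a3))
      placed <- placed + 1L
    }
  }
  n <- length(comp_out)
  if (n == 0L) {
    return(list(centers = matrix(0, 0, 3), axes = matrix(0, 0, 3),
                rot = matrix(0, 0, 9), golgi = matrix(0, 0, 3),
                table = data.frame()))
  }
  # Golgi offsets: concentrated around the local inflow-pointing tangent
  frames <- transport_frames(cl$points)
  golgi <- t(vapply(seq_len(n), function(k) {
    i <- findInterval(svals[k], cl$arclen)
    mu <- -frames$tangent[i, ]  # toward decreasing arc length = inflow
    u <- rnorm(3)
    d <- mu * config$golgi_concentration + u / sqrt(sum(u^2))
    config$golgi_distance * d / sqrt(sum(d^2))
  }, numeric(3)))
  vol <- 4 / 3 * pi * axes[, 1] * axes[, 2] * axes[, 3]
  tab <- data.frame(
    id = seq_len(n),
    z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
    semi_a = axes[, 1], semi_b = axes[, 2], semi_c = axes[, 3],
    arclen = svals, compartment = COMPARTMENTS[comp_out],
    volume_um3 = vol, group = config$group,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(centers = unname(centers), axes = unname(axes), rot = unname(rots),
       golgi = unname(golgi), table = tab)
}

#' @export
print.synthetic_heart <- function(x, ...) {
  cat(sprintf("<synthetic_heart> %s nuclei, %s centerline, grid %s, group '%s'\n",
              nrow(x$truth$nuclei), x$config$centerline_kind,
              paste(dim(x$nuclear), collapse = "x"), x$config$group))
  invisible(x)
}

#' Write a synthetic heart to disk (TIFFs + ground-truth JSON/CSV)
#'
#' @param heart a `synthetic_heart` from [synthesize_heart()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_synthetic_heart <- function(heart, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tiff(heart$nuclear, file.path(outdir, "nuclear.tif"))
  write_tiff(heart$membrane, file.path(outdir, "membrane.tif"))
  write_tiff(heart$compartments, file.path(outdir, "compartments.tif"))
  write_tiff(heart$membrane_regions, file.path(outdir, "membrane_regions.tif"))
  write_tiff(heart$nuclei_true, file.path(outdir, "nuclei_true.tif"))
  tr <- heart$truth
  jsonlite::write_json(list(
    inflow_point = tr$inflow_point, outflow_point = tr$outflow_point,
    analytic_avc_length = tr$analytic_avc_length,
    analytic_centerline_length = tr$analytic_centerline_length,
    analytic_convolutedness = tr$analytic_convolutedness,
    compartment_intervals = tr$compartment_intervals,
    seed = heart$config$seed, group = heart$config$group),
    file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write.csv(tr$nuclei, file.path(outdir, "nuclei_true.csv"), row.names = FALSE)
  write.csv(data.frame(z_um = tr$centerline[, 1], y_um = tr$centerline[, 2],
                       x_um = tr$centerline[, 3], arclen_um = tr$arclen),
            file.path(outdir, "centerline_true.csv"), row.names = FALSE)
  invisible(outdir)
}
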