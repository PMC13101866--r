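#' Estimate unit normals of a membrane mask at anchor points
#'
#' The membrane is locally an (almost) planar sheet of voxels; the normal at
#' an anchor is estimated by a local planar fit: the eigenvector with the
#' smallest eigenvalue of the covariance of membrane-voxel positions within
#' `window_um` of the anchor. Unlike the gradient of a signed distance
#' transform - which vanishes exactly on the membrane mid-surface - this
#' estimator is well conditioned everywhere on the sheet. Anchors farther
#' than two voxels from the membrane, or with too few / degenerate
#' neighbourhoods, are rejected with a warning.
#'
#' @param membrane_mask a [label_volume()] or array (non-zero = membrane)
#'   carrying spacing
#' @param anchor_points n x 3 matrix of anchor positions in um (z, y, x)
#' @param window_um neighbourhood radius of the planar fit (default 4 um;
#'   larger windows average out voxelization, at the cost of curvature bias
#'   on very tight membranes)
#' @return list: `normals` (m x 3 unit vectors), `anchors` (m x 3, the
#'   accepted anchors), `accepted` (logical over input rows)
#' @export
estimate_normals <- function(membrane_mask, anchor_points, window_um = 4) {
  sp <- spacing(membrane_mask)
  d <- dim(membrane_mask)
  anchor_points <- rbind_as_matrix(anchor_points)
  mask <- unclass(membrane_mask) != 0
  n <- nrow(anchor_points)
  normals <- matrix(NA_real_, n, 3)
  ok <- logical(n)
  for (i in seq_len(n)) {
    p <- anchor_points[i, ]
    lo <- pmax(1L, as.integer(floor((p - window_um) / sp - 0.5)) + 1L)
    hi <- pmin(d, as.integer(ceiling((p + window_um) / sp - 0.5)) + 1L)
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    vox <- which(sub)
    if (length(vox) < 8L) next
    zyx0 <- lin_to_zyx0(vox, dim(sub))
    pos <- vox_to_um(sweep(zyx0, 2, lo - 1L, `+`), sp)
    dist <- sqrt(rowSums(sweep(pos, 2, p)^2))
    near <- dist <= window_um
    if (sum(near) < 8L || min(dist) > 2 * max(sp)) next
    pos <- pos[near, , drop = FALSE]
    ev <- eigen(stats::cov(pos), symmetric = TRUE)
    # planar sheet: smallest-eigenvalue direction is the normal; reject
    # degenerate neighbourhoods where the fit has no clear normal direction
    if (ev$values[2] < 4 * ev$values[3] + 1e-12) next
    v <- ev$vectors[, 3]
    ctr <- colMeans(pos)
    if (sum(v * (p - ctr)) < 0) v <- -v  # deterministic orientation
    normals[i, ] <- v / sqrt(sum(v^2))
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok),
            " anchor(s) rejected (far from membrane or degenerate planar fit)")
  list(normals = normals[ok, , drop = FALSE],
       anchors = anchor_points[ok, , drop = FALSE], accepted = ok)
}

#' Sample intensity profiles perpendicular to the membrane
#'
#' For each anchor/normal pair, intensities are sampled by trilinear
#' interpolation from `-half_length` to `+half_length` um along the normal
#' and the per-line maximum is recorded; group statistics run downstream on
#' these per-line maxima (one value per ROI line, as in the original manual
#' procedure of drawing 5-12 perpendicular lines per cell). Lines exiting
#' the image are truncated with a warning. With `single_z = TRUE` normals
#' are projected into the anchor's z-plane first.
#'
#' @param image an [image_stack()]
#' @param anchors n x 3 matrix of anchor positions (um)
#' @param normals n x 3 matrix of unit normals
#' @param half_length half line length in um (default 3)
#' @param step sampling step in um (default 0.25)
#' @param region_labels optional [label_volume()]; each line is tagged with
#'   the label at its anchor
#' @param cell_id optional per-line cell tag
#' @param single_z restrict lines to the anchor's z-plane
#' @param background optional constant offset subtracted from all samples
#'   before the per-line maxima are taken: a number, or `"median"` to use
#'   the image median (robust when most voxels are background). Useful when
#'   ratios of region means are of interest, since a constant pedestal
#'   dilutes contrast. Default: no subtraction (raw maxima).
#' @return a `line_profile_set`: data frame `lines` (anchor, region,
#'   cell_id, max_intensity) plus `profiles` matrix and sample offsets `t`
#' @export
sample_line_profiles <- function(image, anchors, normals, half_length = 3,
                                 step = 0.25, region_labels = NULL,
                                 cell_id = NULL, single_z = FALSE,
                                 background = NULL) {
  if (half_length < step || step <= 0)
    stop("need half_length >= step > 0")
  sp <- spacing(image)
  d <- dim(image)
  anchors <- rbind_as_matrix(anchors)
  normals <- rbind_as_matrix(normals)
  if (nrow(anchors) != nrow(normals))
    stop("anchors and normals must have the same number of rows")
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) stop("normals must be unit length (tol 1e-6)")
  if (single_z) {
    normals[, 1] <- 0
    nl <- sqrt(rowSums(normals^2))
    if (any(nl < 1e-6)) stop("normal lies along z: no in-plane direction")
    normals <- normals / nl
  }
  tt <- seq(-half_length, half_length, by = step)
  n <- nrow(anchors)
  prof <- matrix(NA_real_, n, length(tt))
  for (i in seq_len(n)) {
    pts <- outer(tt, normals[i, ]) + matrix(anchors[i, ], length(tt), 3, byrow = TRUE)
    prof[i, ] <- .trilinear_cpp(as.double(image), d, um_to_vox(pts, sp))
  }
  n_out <- sum(is.na(prof))
  if (n_out > 0)
    warning(sprintf("%d sample(s) outside the image were truncated", n_out))
  if (all(is.na(prof))) stop("all profile samples fall outside the image")
  if (!is.null(background)) {
    bg <- if (identical(background, "median")) median(image) else as.numeric(background)
    prof <- prof - bg
  }
  maxima <- apply(prof, 1, max, na.rm = TRUE)

  region <- rep(NA_integer_, n)
  if (!is.null(region_labels)) {
    vx <- round(um_to_vox(anchors, spacing(region_labels)))
    dl <- dim(region_labels)
    for (ax in 1:3) vx[, ax] <- pmin(pmax(vx[, ax], 0), dl[ax] - 1)
    region <- unclass(region_labels)[cbind(vx[, 1], vx[, 2], vx[, 3]) + 1L]
  }
  lines <- data.frame(
    line_id = seq_len(n),
    z_um = anchors[, 1], y_um = anchors[, 2], x_um = anchors[, 3],
    region = region,
    cell_id = if (is.null(cell_id)) NA else cell_id,
    max_intensity = maxima)
  structure(list(lines = lines, profiles = prof, t = tt,
                 anchors = anchors, normals = normals),
            class = "line_profile_set")
}

#' Sample anchor points on a membrane shell, optionally per region
#'
#' Draws `n` random voxel centres from the shell mask (restricted to one
#' region code when given). Uses the caller's RNG state.
#'
#' @param membrane_labels [label_volume()] of shell voxels (e.g. the
#'   generator's `membrane_regions`)
#' @param n number of anchors
#' @param region optional compartment code or name to restrict to
#' @return n x 3 matrix of anchor positions (um)
#' @export
membrane_anchors <- function(membrane_labels, n, region = NULL) {
  lab <- unclass(membrane_labels)
  sel <- if (is.null(region)) which(lab != 0L) else {
    if (is.character(region)) region <- compartment_code(region)
    which(lab == region)
  }
  if (!length(sel)) stop("no membrane voxels for the requested region")
  take <- sample(sel, min(n, length(sel)))
  vox_to_um(lin_to_zyx0(take, dim(membrane_labels)), spacing(membrane_labels))
}

#' Maximum-intensity-projection readout within a 2D ROI
#'
#' Projects the stack along z (per-pixel maximum) and returns the maximum
#' projected intensity inside the ROI, as used for RNAscope signal readout.
#'
#' @param stack an [image_stack()]
#' @param roi ny x nx logical matrix (TRUE = inside ROI)
#' @return maximum intensity within the ROI
#' @export
max_projection_intensity <- function(stack, roi) {
  d <- dim(stack)
  if (!is.matrix(roi) || !all(dim(roi) == d[2:3]))
    stop("`roi` must be a ny x nx logical matrix matching the stack")
  roi <- roi != 0
  if (!any(roi)) stop("empty ROI")
  mip <- unclass(stack)[1, , ]
  if (d[1] > 1)
    for (z in 2:d[1]) mip <- pmax(mip, unclass(stack)[z, , ])
  max(mip[roi])
}

#' Normalize intensity values to a reference mean
#'
#' Divides by the mean of the reference values (e.g. "normalized to mean
#' AVC value"); the reference's normalized mean is exactly 1.
#'
#' @param values numeric vector
#' @param reference_values non-empty numeric reference with positive mean
#' @return normalized values
#' @export
normalize_to_reference <- function(values, reference_values) {
  if (!length(reference_values)) stop("empty reference")
  m <- mean(reference_values)
  if (!is.finite(m) || m <= 0) stop("reference mean must be positive")
  values / m
}
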