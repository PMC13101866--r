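#' Resample a volume to isotropic voxels
#'
#' Labels are resampled with nearest-neighbour interpolation, intensities
#' with trilinear interpolation. Output voxel counts are chosen so the
#' physical extent is preserved within half a target voxel per axis. The
#' morphometry routines follow the convention of working at 2 um isotropic.
#'
#' @param x an [image_stack()] or [label_volume()]
#' @param target_edge isotropic voxel edge in um (default 2)
#' @return resampled object of the same class
#' @export
resample_isotropic <- function(x, target_edge = 2) {
  if (target_edge <= 0) stop("`target_edge` must be positive")
  sp <- spacing(x)
  d <- dim(x)
  extent <- d * sp
  if (any(extent < target_edge))
    stop(sprintf("target edge %.3g um is coarser than the object extent (%s um)",
                 target_edge, paste(signif(extent, 4), collapse = " x ")))
  nd <- pmax(1L, as.integer(round(extent / target_edge)))
  # per-axis continuous source coordinates of the output voxel centres
  coords <- lapply(1:3, function(ax)
    ((seq_len(nd[ax]) - 0.5) * target_edge) / sp[ax] - 0.5)
  if (inherits(x, "label_volume")) {
    idx <- lapply(1:3, function(ax)
      pmin(pmax(as.integer(round(coords[[ax]])), 0L), d[ax] - 1L) + 1L)
    out <- unclass(x)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    label_volume(array(as.integer(out), nd), rep(target_edge, 3))
  } else {
    pts <- cbind(rep(coords[[1]], times = nd[2] * nd[3]),
                 rep(rep(coords[[2]], each = nd[1]), times = nd[3]),
                 rep(coords[[3]], each = nd[1] * nd[2]))
    pts[, 1] <- pmin(pmax(pts[, 1], 0), d[1] - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), d[2] - 1)
    pts[, 3] <- pmin(pmax(pts[, 3], 0), d[3] - 1)
    vals <- .trilinear_cpp(as.double(x), d, pts)
    image_stack(array(vals, nd), rep(target_edge, 3), channel = attr(x, "channel"))
  }
}

#' Centroid of the voxel-face interface between two compartments
#'
#' The interface is the set of voxel-face midpoints where an `a`-labelled
#' voxel 6-neighbours a `b`-labelled voxel; its centroid is the mean of the
#' midpoints in um.
#'
#' @param compartments a [label_volume()] of compartment codes
#' @param a,b compartment codes (integers) or names
#' @return list: `pair`, `centroid` (um, z/y/x order), `face_count`
#' @export
extract_interface <- function(compartments, a, b) {
  if (is.character(a)) a <- compartment_code(a)
  if (is.character(b)) b <- compartment_code(b)
  sp <- spacing(compartments)
  d <- dim(compartments)
  lab <- unclass(compartments)
  mids <- NULL
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    lo <- switch(ax, lab[-n, , , drop = FALSE], lab[, -n, , drop = FALSE],
                 lab[, , -n, drop = FALSE])
    hi <- switch(ax, lab[-1, , , drop = FALSE], lab[, -1, , drop = FALSE],
                 lab[, , -1, drop = FALSE])
    hit <- which((lo == a & hi == b) | (lo == b & hi == a))
    if (!length(hit)) next
    # 0-based coords in the shrunken array equal the lower voxel's coords
    zyx0 <- lin_to_zyx0(hit, dim(lo))
    m <- vox_to_um(zyx0, sp)
    m[, ax] <- m[, ax] + sp[ax] / 2  # face midpoint between the voxel pair
    mids <- rbind(mids, m)
  }
  if (is.null(mids))
    stop(sprintf("compartments %s and %s are not 6-adjacent",
                 COMPARTMENTS[a], COMPARTMENTS[b]))
  list(pair = c(a, b), centroid = colMeans(mids), face_count = nrow(mids))
}

#' AVC length from compartment interface centroids
#'
#' Euclidean distance between the atrium|AVC and AVC|ventricle interface
#' centroids.
#'
#' @param compartments a [label_volume()] with the five-class convention
#' @return AVC length in um
#' @export
avc_length <- function(compartments) {
  present <- unique(as.vector(unclass(compartments)))
  for (code in 2:4)
    if (!code %in% present)
      stop(sprintf("compartment '%s' absent from label volume", COMPARTMENTS[code]))
  c1 <- extract_interface(compartments, 2L, 3L)$centroid
  c2 <- extract_interface(compartments, 3L, 4L)$centroid
  sqrt(sum((c1 - c2)^2))
}

#' Central line of the lumen between the inflow and outflow points
#'
#' Minimal-cost voxel path (26-connectivity) from inflow to outflow where
#' the per-voxel cost is `1 / (1 + d)^2` with `d` the distance to the lumen
#' boundary in um, which keeps the path on the lumen's medial ridge. The
#' voxel path is smoothed by a moving average (default window 5) with the
#' endpoints pinned, and the length is the sum of segment lengths in um.
#'
#' @param lumen_mask a [label_volume()] / logical or integer array (non-zero
#'   = lumen) carrying spacing
#' @param inflow_point,outflow_point 3D points in um (z, y, x)
#' @param smooth_window moving-average window (voxels) for the polyline
#' @param snap_tolerance how far (um) an endpoint may sit from the lumen
#' @return list: `polyline` (n x 3 um), `length` (um)
#' @export
central_line <- function(lumen_mask, inflow_point, outflow_point,
                         smooth_window = 5L, snap_tolerance = NULL) {
  sp <- spacing(lumen_mask)
  d <- dim(lumen_mask)
  if (is.null(snap_tolerance)) snap_tolerance <- 2 * max(sp)
  mask <- array(as.integer(unclass(lumen_mask) != 0), d)
  if (!any(mask == 1L)) stop("lumen mask is empty")
  if (all(inflow_point == outflow_point))
    return(list(polyline = matrix(inflow_point, 1, 3), length = 0))
  sel <- which(mask == 1L)
  pos <- vox_to_um(lin_to_zyx0(sel, d), sp)
  snap <- function(p) {
    dd <- sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2)
    i <- which.min(dd)
    if (dd[i] > snap_tolerance + 1e-9)
      stop(sprintf("endpoint (%.1f, %.1f, %.1f) um lies %.2f um from the lumen (tolerance %.2f)",
                   p[1], p[2], p[3], dd[i], snap_tolerance))
    sel[i]
  }
  src <- snap(inflow_point)
  dst <- snap(outflow_point)
  dt <- .edt3d_cpp(mask, d, sp)
  cost <- 1 / (1 + dt)^2
  path <- .dijkstra_path_cpp(as.double(cost), d, sp, mask, src, dst)
  if (!length(path))
    stop("inflow and outflow are disconnected in the lumen mask")
  poly <- vox_to_um(lin_to_zyx0(path, d), sp)
  # anchor the polyline at the exact requested endpoints (the voxel path
  # starts/ends at snapped voxel centres up to snap_tolerance away)
  poly <- rbind(inflow_point, poly, outflow_point)
  rownames(poly) <- NULL
  if (smooth_window > 1L && nrow(poly) > 2L) {
    w <- as.integer(smooth_window)
    pad <- w %/% 2L
    padded <- rbind(matrix(poly[1, ], pad, 3, byrow = TRUE), poly,
                    matrix(poly[nrow(poly), ], pad, 3, byrow = TRUE))
    sm <- apply(padded, 2, function(v)
      as.numeric(filter(v, rep(1 / w, w), sides = 2)))
    sm <- sm[(pad + 1):(pad + nrow(poly)), , drop = FALSE]
    sm[1, ] <- poly[1, ]
    sm[nrow(sm), ] <- poly[nrow(poly), ]
    poly <- sm
  }
  len <- sum(sqrt(rowSums(diff(poly)^2)))
  list(polyline = poly, length = len)
}

#' Convolutedness (looping ratio) of a central line
#'
#' Ratio of the central-line length to the straight inflow-outflow distance;
#' larger values mean a more looped heart. At least `1 - 0.01` up to
#' voxelization error.
#'
#' @param central_line result of [central_line()] (or a bare length in um)
#' @param inflow_point,outflow_point 3D points in um
#' @return dimensionless ratio
#' @export
convolutedness <- function(central_line, inflow_point, outflow_point) {
  len <- if (is.list(central_line)) central_line$length else as.numeric(central_line)
  if (len <= 0) stop("central-line length must be positive")
  chord <- sqrt(sum((outflow_point - inflow_point)^2))
  if (chord <= 1e-9) stop("coincident inflow/outflow points: ratio undefined")
  len / chord
}

#' Full morphometry of a compartment-labelled heart lumen
#'
#' Resamples to isotropic voxels (default 2 um), locates the four
#' compartment interfaces, defines the inflow point as the
#' pre-atrium|atrium interface centroid and the outflow point as the
#' ventricle|postventricle centroid, measures the AVC length, traces the
#' central line between inflow and outflow, and computes the convolutedness
#' ratio.
#'
#' @param compartments a [label_volume()] with all five compartments
#' @param target_edge isotropic resampling edge in um (NULL = no resampling)
#' @param smooth_window polyline smoothing window for [central_line()]
#' @return a `morphometry_result` list: `avc_length`, `inflow_point`,
#'   `outflow_point`, `straight_distance`, `central_line` (polyline),
#'   `central_line_length`, `convolutedness`, `interfaces`
#' @export
heart_morphometry <- function(compartments, target_edge = 2, smooth_window = 5L) {
  if (!is.null(target_edge))
    compartments <- resample_isotropic(compartments, target_edge)
  inter <- list(
    inflow = extract_interface(compartments, 1L, 2L),
    atrium_avc = extract_interface(compartments, 2L, 3L),
    avc_ventricle = extract_interface(compartments, 3L, 4L),
    outflow = extract_interface(compartments, 4L, 5L))
  inflow <- inter$inflow$centroid
  outflow <- inter$outflow$centroid
  avc <- sqrt(sum((inter$atrium_avc$centroid - inter$avc_ventricle$centroid)^2))
  cl <- central_line(compartments, inflow, outflow, smooth_window = smooth_window)
  structure(list(
    avc_length = avc,
    inflow_point = inflow, outflow_point = outflow,
    straight_distance = sqrt(sum((outflow - inflow)^2)),
    central_line = cl$polyline, central_line_length = cl$length,
    convolutedness = convolutedness(cl, inflow, outflow),
    interfaces = inter), class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_result> AVC length %.2f um, central line %.2f um, ",
                     "straight %.2f um, convolutedness %.3f\n"),
              x$avc_length, x$central_line_length, x$straight_distance,
              x$convolutedness))
  invisible(x)
}
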