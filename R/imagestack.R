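#' 3D intensity stack with physical voxel spacing
#'
#' Wraps a numeric 3D array in (z, y, x) axis order together with the
#' per-axis voxel spacing in micrometres. The voxel centre of 0-based index
#' `v` lies at `(v + 0.5) * spacing`.
#'
#' @param data numeric 3D array, axis order (z, y, x)
#' @param spacing numeric length-3, micrometres per voxel edge (z, y, x)
#' @param channel optional channel name
#' @return an `image_stack` object
#' @export
image_stack <- function(data, spacing = c(1, 1, 1), channel = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  storage.mode(data) <- "double"
  spacing <- check_spacing(spacing)
  structure(data, spacing = spacing, channel = channel,
            class = c("image_stack", "array"))
}

#' Integer-labelled 3D volume (0 = background)
#'
#' Same spacing contract as [image_stack()]; used for nucleus instances and
#' for the five anatomical compartments (codes 1 = pre-atrium, 2 = atrium,
#' 3 = AVC, 4 = ventricle, 5 = postventricle).
#'
#' @param data integer 3D array, non-negative, axis order (z, y, x)
#' @param spacing numeric length-3, micrometres per voxel edge (z, y, x)
#' @return a `label_volume` object
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (is.double(data)) {
    if (any(data != round(data), na.rm = TRUE))
      stop("label volume must contain integer labels")
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) stop("label volume must be integer-valued")
  if (any(data < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  spacing <- check_spacing(spacing)
  structure(data, spacing = spacing, class = c("label_volume", "array"))
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (z, y, x) in um")
  spacing
}

#' Voxel spacing in micrometres
#' @param x an `image_stack` or `label_volume`
#' @return numeric length-3 (z, y, x)
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) stop("object carries no voxel spacing")
  s
}

#' Physical volume of one voxel in cubic micrometres
#' @param x an `image_stack` or `label_volume`
#' @export
voxel_volume <- function(x) prod(spacing(x))

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), spacing %s um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(spacing(x), 4), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x), spacing %s um, %d labels\n",
              d[1], d[2], d[3], paste(signif(spacing(x), 4), collapse = " x "),
              length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

# linear (1-based) index -> n x 3 matrix of 0-based (z, y, x) voxel indices
lin_to_zyx0 <- function(idx1, dim) {
  idx0 <- idx1 - 1L
  z <- idx0 %% dim[1]
  rest <- idx0 %/% dim[1]
  y <- rest %% dim[2]
  x <- rest %/% dim[2]
  cbind(z = z, y = y, x = x)
}

# 0-based voxel indices (n x 3) -> physical um at voxel centres
vox_to_um <- function(zyx0, spacing) {
  sweep(zyx0 + 0.5, 2L, spacing, `*`)
}

# physical um (n x 3) -> continuous 0-based voxel coordinates
um_to_vox <- function(um, spacing) {
  sweep(um, 2L, spacing, `/`) - 0.5
}
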