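#' Assign nuclei to anatomical compartments along the centerline
#'
#' Each nucleus gets the compartment of its nearest centerline arc-length
#' position (intervals in the five-class convention). Nuclei farther than
#' `cutoff` um from the lumen surface are marked `"unassigned"`; the lumen
#' surface is approximated by the per-compartment tube radius when supplied
#' (otherwise the cutoff is measured from the centerline itself).
#'
#' @param nuclei data frame with `z_um`, `y_um`, `x_um` (e.g. from
#'   [measure_nuclei()])
#' @param centerline list with `points` (n x 3 um) and `arclen`, e.g. from
#'   [make_centerline()] or a `heart_ground_truth`
#' @param intervals data frame with `code`, `arclen_lo`, `arclen_hi`
#'   (five-compartment arc-length intervals)
#' @param cutoff maximum distance from the lumen in um (default 20)
#' @param tube_radius optional lumen radius per compartment code (um)
#' @return `nuclei` with `compartment` and `dist_centerline_um` columns
#' @export
assign_compartment <- function(nuclei, centerline, intervals, cutoff = 20,
                               tube_radius = NULL) {
  if (inherits(centerline, "heart_ground_truth")) {
    if (missing(intervals) || is.null(intervals))
      intervals <- centerline$compartment_intervals
    centerline <- list(points = centerline$centerline, arclen = centerline$arclen)
  }
  pts <- centerline$points
  if (is.null(pts) || nrow(pts) < 2L) stop("centerline with >= 2 points required")
  if (nrow(nuclei) == 0L) {
    nuclei$compartment <- character(0)
    nuclei$dist_centerline_um <- numeric(0)
    return(nuclei)
  }
  P <- as.matrix(nuclei[, c("z_um", "y_um", "x_um")])
  # nearest centerline sample per nucleus
  nn <- vapply(seq_len(nrow(P)), function(i) {
    d2 <- (pts[, 1] - P[i, 1])^2 + (pts[, 2] - P[i, 2])^2 + (pts[, 3] - P[i, 3])^2
    which.min(d2)
  }, integer(1))
  dist <- sqrt(rowSums((pts[nn, , drop = FALSE] - P)^2))
  s <- centerline$arclen[nn]
  code <- vapply(s, function(si) {
    hit <- which(si >= intervals$arclen_lo & si <= intervals$arclen_hi)
    if (length(hit)) intervals$code[hit[1]] else NA_integer_
  }, integer(1))
  surf_dist <- dist
  if (!is.null(tube_radius))
    surf_dist <- pmax(0, dist - tube_radius[pmax(code, 1L)])
  comp <- ifelse(!is.na(code) & surf_dist <= cutoff, COMPARTMENTS[code], "unassigned")
  nuclei$compartment <- comp
  nuclei$dist_centerline_um <- dist
  nuclei
}

#' Normalize nucleus volumes to a reference group's mean
#'
#' Divides every volume by the mean volume of the reference subset
#' (reference group, optionally restricted to one compartment), matching the
#' figure convention "normalized to mean control value". The reference
#' subset's normalized mean is exactly 1.
#'
#' @param records data frame with a volume column and `group` (and
#'   `compartment` when `reference_compartment` is used)
#' @param reference_group group id of the reference (e.g. `"control"`)
#' @param reference_compartment compartment of the reference subset
#'   (default `"AVC"`; NULL = all compartments)
#' @param value_col name of the volume column
#' @return `records` with a `volume_norm` column; the reference mean is
#'   attached as attribute `reference_mean`
#' @export
normalize_volumes <- function(records, reference_group,
                              reference_compartment = "AVC",
                              value_col = "volume_um3") {
  if (!value_col %in% names(records)) stop("no column `", value_col, "` in records")
  sel <- records$group == reference_group
  if (!is.null(reference_compartment))
    sel <- sel & records$compartment == reference_compartment
  if (!any(sel)) stop(sprintf("empty reference subset (group '%s', compartment %s)",
                              reference_group,
                              if (is.null(reference_compartment)) "any"
                              else sprintf("'%s'", reference_compartment)))
  ref_mean <- mean(records[[value_col]][sel])
  records$volume_norm <- records[[value_col]] / ref_mean
  attr(records, "reference_mean") <- ref_mean
  records
}

#' Classify nucleus-to-Golgi polarity against the inflow axis
#'
#' The angle between the nucleus-to-Golgi vector and the inflow-directed
#' axis determines the call: `inflow` if the angle is at most
#' `cone_half_angle`, `outflow` if at least `180 - cone_half_angle`, else
#' `unpolarized`. Zero-length Golgi offsets are called `unpolarized` with a
#' warning.
#'
#' @param nucleus_centroid n x 3 matrix of nucleus positions (um)
#' @param golgi_centroid n x 3 matrix of Golgi positions (um)
#' @param inflow_axis length-3 vector pointing toward the inflow
#' @param cone_half_angle cone half-angle in degrees (default 60; the
#'   original visual classification used no explicit threshold)
#' @return data frame: `nucleus_id`, `angle_deg` in [0, 180], `call`
#' @export
classify_polarity <- function(nucleus_centroid, golgi_centroid, inflow_axis,
                              cone_half_angle = 60) {
  nucleus_centroid <- rbind_as_matrix(nucleus_centroid)
  golgi_centroid <- rbind_as_matrix(golgi_centroid)
  if (!all(dim(nucleus_centroid) == dim(golgi_centroid)))
    stop("nucleus and Golgi centroid matrices must have matching shape")
  a <- sqrt(sum(inflow_axis^2))
  if (a == 0) stop("inflow_axis must be non-zero")
  axis <- inflow_axis / a
  off <- golgi_centroid - nucleus_centroid
  nrm <- sqrt(rowSums(off^2))
  zero <- nrm < 1e-12
  if (any(zero))
    warning(sum(zero), " zero-length Golgi offset(s): called unpolarized")
  cosang <- (off %*% axis)[, 1] / ifelse(zero, 1, nrm)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  call <- ifelse(ang <= cone_half_angle, "inflow",
                 ifelse(ang >= 180 - cone_half_angle, "outflow", "unpolarized"))
  call[zero] <- "unpolarized"
  ang[zero] <- NA_real_
  data.frame(nucleus_id = seq_len(nrow(off)), angle_deg = ang, call = call)
}

rbind_as_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Polarity class percentages
#'
#' @param calls output of [classify_polarity()] (or its `call` column)
#' @return named percentages over inflow / outflow / unpolarized, summing to
#'   100
#' @export
polarity_percentages <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$call
  lev <- c("inflow", "outflow", "unpolarized")
  100 * table(factor(calls, levels = lev)) / length(calls)
}

#' Two-sided group comparison tests used in the figure legends
#'
#' Supports `mann_whitney` (Wilcoxon rank-sum; the exact permutation null is
#' enumerated when both groups have at most `exact_max` observations, the
#' tie-corrected normal approximation with continuity correction otherwise),
#' `t_test` (unpaired, equal variances) and `kruskal_wallis` (3 or more
#' groups).
#'
#' @param values_by_group named list of numeric vectors (2 groups, or more
#'   for Kruskal-Wallis), each of size at least 2
#' @param test one of `"mann_whitney"`, `"t_test"`, `"kruskal_wallis"`
#' @param exact_max exact-enumeration size limit per group for Mann-Whitney
#' @return a `group_comparison` list: `test`, `statistic`, `p_value`,
#'   `group_sizes`, `method_detail`
#' @export
run_group_test <- function(values_by_group,
                           test = c("mann_whitney", "t_test", "kruskal_wallis"),
                           exact_max = 8L) {
  supported <- c("mann_whitney", "t_test", "kruskal_wallis")
  if (!is.character(test) || !test[1] %in% supported)
    stop("unsupported test '", test[1], "'; supported: ",
         paste(supported, collapse = ", "))
  test <- test[1]
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("values_by_group must be a list of at least 2 groups")
  sizes <- vapply(values_by_group, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  if (test %in% c("mann_whitney", "t_test") && length(values_by_group) != 2L)
    stop(test, " compares exactly 2 groups")

  if (test == "mann_whitney") {
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    if (length(x) <= exact_max && length(y) <= exact_max) {
      res <- mann_whitney_exact(x, y)
      detail <- "exact permutation null (full enumeration)"
    } else {
      wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
      res <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
      detail <- "normal approximation with continuity correction"
    }
    out <- list(test = test, statistic = res$statistic, p_value = res$p_value,
                group_sizes = sizes, method_detail = detail)
  } else if (test == "t_test") {
    tt <- t.test(values_by_group[[1]], values_by_group[[2]], var.equal = TRUE)
    out <- list(test = test, statistic = unname(tt$statistic),
                p_value = tt$p.value, group_sizes = sizes,
                method_detail = "unpaired two-sample t (equal variances)")
  } else {
    kt <- kruskal.test(values_by_group)
    out <- list(test = test, statistic = unname(kt$statistic),
                p_value = kt$p.value, group_sizes = sizes,
                method_detail = "Kruskal-Wallis rank sum")
  }
  structure(out, class = "group_comparison")
}

# exact two-sided Mann-Whitney by full enumeration of C(n1+n2, n1) labelings;
# uses midranks, so ties are handled; p = share of labelings whose U deviates
# from n1*n2/2 at least as much as the observed U
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mu)
  cmb <- combn(n1 + n2, n1)
  devs <- abs(apply(cmb, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2 - mu)
  list(statistic = u_obs, p_value = mean(devs >= dev_obs - 1e-12))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g (n = %s; %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = ", "), x$method_detail))
  invisible(x)
}
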