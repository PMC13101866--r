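test_that("normals on a plane membrane are axial within 2 degrees", {
  arr <- array(0L, c(40, 24, 24)); arr[20:21, , ] <- 1L
  mk <- label_volume(arr, c(1, 1, 1))
  anchors <- cbind(20.5, c(8, 12, 16), c(8, 12, 16))
  nr <- estimate_normals(mk, anchors)
  expect_equal(nrow(nr$normals), 3L)
  ang <- acos(pmin(1, abs(nr$normals[, 1]))) * 180 / pi
  expect_lt(max(ang), 2)
})

test_that("normals on a spherical shell are radial within 5 degrees", {
  ctr <- c(20.5, 20.5, 20.5)
  outer_s <- make_sphere_stack(c(41, 41, 41), center = ctr, radius = 12)
  inner_s <- make_sphere_stack(c(41, 41, 41), center = ctr, radius = 10)
  shell <- label_volume(array(as.integer(unclass(outer_s) > 0 & unclass(inner_s) == 0),
                              c(41, 41, 41)), c(1, 1, 1))
  set.seed(2)
  u <- matrix(rnorm(3 * 30), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  anchors <- sweep(11 * u, 2, ctr, `+`)
  nr <- estimate_normals(shell, anchors)
  expect_gt(nrow(nr$normals), 20)
  radial <- anchors[nr$accepted, , drop = FALSE] - matrix(ctr, nrow(nr$normals), 3, byrow = TRUE)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(nr$normals * radial)))) * 180 / pi
  expect_lt(max(ang), 5)

  # far anchors are rejected with a warning
  expect_warning(far <- estimate_normals(shell, rbind(c(2, 2, 2))), "rejected")
  expect_equal(nrow(far$normals), 0L)
})

test_that("line profiles on a constant field return the constant", {
  img <- image_stack(array(4.2, c(20, 20, 20)), c(1, 1, 1))
  lp <- sample_line_profiles(img, rbind(c(10, 10, 10)), rbind(c(0, 0, 1)))
  expect_equal(lp$lines$max_intensity, 4.2)
  expect_true(all(abs(lp$profiles - 4.2) < 1e-12))
})

test_that("per-line maxima match a direct voxel-max oracle on a Gaussian ridge", {
  # membrane-like Gaussian ridge centred at x = 15 um
  d <- c(21, 21, 31)
  x_um <- (seq_len(d[3]) - 0.5)
  ridge <- array(rep(100 * exp(-((x_um - 15)^2) / (2 * 1.5^2)),
                     each = d[1] * d[2]), d)
  img <- image_stack(ridge, c(1, 1, 1))
  anchors <- cbind(10.5, c(6.5, 10.5, 14.5), 15.2)
  normals <- matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE)
  lp <- sample_line_profiles(img, anchors, normals, half_length = 4, step = 0.1)
  direct_max <- max(ridge)  # the analytic normal passes through the ridge crest
  expect_lt(max(abs(lp$lines$max_intensity - direct_max) / direct_max), 0.05)
  # peak position within one sampling step plus half a voxel (the discrete
  # ridge is flat between the two voxel centres flanking the crest)
  t_peak <- lp$t[apply(lp$profiles, 1, which.max)]
  expect_lt(max(abs(t_peak - (15 - 15.2))), 0.1 + 0.5 + 1e-9)
})

test_that("per-line max is invariant to reversing the normal", {
  h <- small_heart(seed = 19)
  set.seed(3)
  anchors <- membrane_anchors(h$membrane_regions, 10, "atrium")
  nr <- suppressWarnings(estimate_normals(h$membrane_regions, anchors))
  lp1 <- sample_line_profiles(h$membrane, nr$anchors, nr$normals)
  lp2 <- sample_line_profiles(h$membrane, nr$anchors, -nr$normals)
  expect_equal(lp1$lines$max_intensity, lp2$lines$max_intensity, tolerance = 1e-9)
  # max_intensity equals the max of its own samples exactly
  expect_equal(lp1$lines$max_intensity,
               apply(lp1$profiles, 1, max, na.rm = TRUE))
})

test_that("profiles peak within a sampling step of the true membrane surface", {
  h <- synthesize_heart(synthetic_config(
    grid_shape = c(48, 100, 150),
    centerline_params = list(radius = 50, turn_fraction = 0.5),
    tube_radius_by_compartment = c(12, 16, 8, 18, 12),
    n_nuclei_by_compartment = rep(0L, 5),
    noise = list(gaussian_sd = 0, poisson_scale = 0), seed = 23))
  set.seed(4)
  anchors <- membrane_anchors(h$membrane_regions, 25, "ventricle")
  nr <- suppressWarnings(estimate_normals(h$membrane_regions, anchors))
  lp <- sample_line_profiles(h$membrane, nr$anchors, nr$normals,
                             half_length = 4, step = 0.25)
  # signed distance from each anchor to the membrane mid-surface (radius 18)
  cl_pts <- h$truth$centerline
  t_true <- vapply(seq_len(nrow(nr$anchors)), function(i) {
    p <- nr$anchors[i, ]
    dmin <- sqrt(min(colSums((t(cl_pts) - p)^2)))
    dmin - 18
  }, numeric(1))
  t_peak <- lp$t[apply(lp$profiles, 1, which.max)]
  # outward normals: peak at +t_true or -t_true depending on orientation
  off <- pmin(abs(t_peak - t_true), abs(t_peak + t_true))
  # within one sampling step plus half a voxel of discretization
  expect_lt(median(off), 0.25 + 0.5)
  expect_lt(mean(off <= 0.25 + 0.87), 1 + 1e-9)
  expect_gt(mean(off <= 0.25 + 0.87), 0.9)
})

test_that("region contrast is unbiased across 20 generator seeds", {
  # scaled-down hearts (same 2x programmed AVC/atrium membrane contrast)
  ratios <- vapply(1:20, function(sd) {
    h <- small_heart(seed = 300 + sd)
    set.seed(400 + sd)
    means <- vapply(c("AVC", "atrium"), function(rg) {
      anchors <- membrane_anchors(h$membrane_regions, 30, rg)
      nr <- suppressWarnings(estimate_normals(h$membrane_regions, anchors))
      lp <- sample_line_profiles(h$membrane, nr$anchors, nr$normals,
                                 background = "median")
      mean(lp$lines$max_intensity)
    }, numeric(1))
    means[["AVC"]] / means[["atrium"]]
  }, numeric(1))
  expect_gte(mean(ratios) / 2, 0.9)
  expect_lte(mean(ratios) / 2, 1.1)
})

test_that("truncation at the image border warns and still returns maxima", {
  img <- image_stack(array(1, c(10, 10, 10)), c(1, 1, 1))
  expect_warning(
    lp <- sample_line_profiles(img, rbind(c(5, 5, 1)), rbind(c(0, 0, 1)),
                               half_length = 5, step = 0.5),
    "truncated")
  expect_equal(lp$lines$max_intensity, 1)
})

test_that("max projection readout handles hot voxels, zeros, and z-stacks", {
  arr <- array(0, c(3, 8, 8))
  arr[2, 4, 5] <- 9
  st <- image_stack(arr, c(1, 1, 1))
  roi <- matrix(TRUE, 8, 8)
  expect_equal(max_projection_intensity(st, roi), 9)
  expect_equal(max_projection_intensity(image_stack(array(0, c(3, 8, 8)),
                                                    c(1, 1, 1)), roi), 0)
  arr2 <- array(0, c(2, 4, 4)); arr2[1, 2, 2] <- 3; arr2[2, 2, 2] <- 7
  expect_equal(max_projection_intensity(image_stack(arr2, c(1, 1, 1)),
                                        matrix(TRUE, 4, 4)), 7)
  expect_error(max_projection_intensity(st, matrix(FALSE, 8, 8)), "empty ROI")
})

test_that("normalize_to_reference divides by the reference mean", {
  expect_equal(normalize_to_reference(c(2, 6), 4), c(0.5, 1.5))
  expect_equal(mean(normalize_to_reference(c(3, 5), c(3, 5))), 1)
  expect_error(normalize_to_reference(1:3, numeric(0)), "empty")
  expect_error(normalize_to_reference(1:3, c(-2, 0)), "positive")
})
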