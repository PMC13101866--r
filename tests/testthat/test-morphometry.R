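test_that("isotropic resampling preserves volume and is identity when trivial", {
  # ~1000 um^3 mask at anisotropic spacing, resampled to 2 um isotropic
  arr <- array(0L, c(20, 24, 24))
  arr[4:8, 5:18, 5:18] <- 1L           # 5*2 x 14*0.5 x 14*0.5 um = 490 um^3
  arr[10:17, 3:20, 3:20] <- 2L
  lv <- label_volume(arr, c(2, 0.5, 0.5))
  vol_in <- sum(unclass(lv) > 0) * voxel_volume(lv)
  out <- resample_isotropic(lv, 2)
  vol_out <- sum(unclass(out) > 0) * voxel_volume(out)
  expect_lt(abs(vol_out / vol_in - 1), 0.10)

  iso <- label_volume(array(sample(0:3, 6^3, TRUE), c(6, 6, 6)), c(2, 2, 2))
  expect_identical(as.vector(unclass(resample_isotropic(iso, 2))),
                   as.vector(unclass(iso)))

  cube <- label_volume(array(1L, c(2, 2, 2)), c(1, 1, 1))
  one <- resample_isotropic(cube, 2)
  expect_equal(dim(one), c(1L, 1L, 1L))
  expect_equal(as.vector(unclass(one)), 1L)

  expect_error(resample_isotropic(cube, 50), "coarser")
  # intensity path: trilinear resampling of a smooth ramp stays exact
  ramp <- image_stack(array(rep(seq_len(16), each = 64), c(8, 8, 16)), c(1, 1, 1))
  r2 <- resample_isotropic(ramp, 2)
  expect_equal(dim(r2), c(4L, 4L, 8L))
  expect_equal(as.vector(r2[2, 2, ]), seq(1.5, 15.5, by = 2))
})

test_that("interface centroids sit on the separating plane", {
  arr <- array(1L, c(50, 21, 21))
  arr[26:50, , ] <- 2L                  # plane z = 50 um in a 100 um grid
  lv <- label_volume(arr, c(2, 2, 2))
  ic <- extract_interface(lv, 1L, 2L)
  expect_equal(unname(ic$centroid[1]), 50, tolerance = 1e-9)
  expect_equal(unname(ic$centroid[2]), 21, tolerance = 1e-9)  # grid centre in y
  expect_equal(ic$face_count, 21 * 21)

  arr2 <- array(0L, c(10, 10, 10))
  arr2[1:2, , ] <- 1L
  arr2[8:10, , ] <- 2L                  # disjoint labels
  expect_error(extract_interface(label_volume(arr2, c(1, 1, 1)), 1L, 2L),
               "not 6-adjacent")
})

test_that("avc_length matches generator intervals and arc chords", {
  # straight tube with a 20 um AVC span
  h <- synthesize_heart(quiet_config(
    grid_shape = c(36, 36, 260), centerline_kind = "straight",
    centerline_params = list(length = 200),
    compartment_fractions = c(0.25, 0.25, 0.10, 0.25, 0.15),
    tube_radius_by_compartment = rep(10, 5)))
  got <- avc_length(resample_isotropic(h$compartments, 2))
  expect_lt(abs(got - 20), 4)  # +/- 2 voxels at 2 um

  # arc tube: AVC spanning 30 um of arc on radius 100 -> chord 2R sin(15/100)
  s_avc <- 30 / (0.6 * pi * 100)
  h2 <- synthesize_heart(quiet_config(
    grid_shape = c(36, 140, 220), centerline_kind = "arc",
    centerline_params = list(radius = 100, turn_fraction = 0.3),
    compartment_fractions = c(0.3, 0.25, s_avc, 0.25, 0.2 - s_avc),
    tube_radius_by_compartment = rep(10, 5)))
  chord <- 2 * 100 * sin(15 / 100)
  got2 <- avc_length(resample_isotropic(h2$compartments, 2))
  expect_lt(abs(got2 / chord - 1), 0.05)

  # AVC label absent
  arr <- array(0L, c(8, 8, 8)); arr[, , 1:4] <- 1L; arr[, , 5:8] <- 2L
  expect_error(avc_length(label_volume(arr, c(1, 1, 1))), "absent")
})

test_that("central line length matches cylinder axis and arc closed forms", {
  h <- synthesize_heart(quiet_config(
    grid_shape = c(36, 36, 180), centerline_kind = "straight",
    centerline_params = list(length = 120),
    tube_radius_by_compartment = rep(10, 5)))
  lum <- resample_isotropic(h$compartments, 2)
  cl <- central_line(lum, h$truth$inflow_point, h$truth$outflow_point)
  expect_lt(abs(cl$length / 120 - 1), 0.02)

  h2 <- synthesize_heart(quiet_config(
    grid_shape = c(36, 100, 150), centerline_kind = "arc",
    centerline_params = list(radius = 50, turn_fraction = 0.5),
    tube_radius_by_compartment = rep(10, 5)))
  lum2 <- resample_isotropic(h2$compartments, 2)
  cl2 <- central_line(lum2, h2$truth$inflow_point, h2$truth$outflow_point)
  expect_lt(abs(cl2$length / (pi * 50) - 1), 0.05)

  # degenerate: coincident endpoints give a zero-length line
  z <- central_line(lum, h$truth$inflow_point, h$truth$inflow_point)
  expect_equal(z$length, 0)

  # endpoints disconnected in the mask
  arr <- array(0L, c(10, 10, 30))
  arr[4:6, 4:6, 1:10] <- 1L
  arr[4:6, 4:6, 21:30] <- 1L
  expect_error(central_line(label_volume(arr, c(1, 1, 1)),
                            c(5, 5, 2), c(5, 5, 28)), "disconnected")
})

test_that("convolutedness matches arc/chord closed forms", {
  h <- synthesize_heart(quiet_config(
    grid_shape = c(36, 110, 110), centerline_kind = "arc",
    centerline_params = list(radius = 50, turn_fraction = 0.25),
    tube_radius_by_compartment = rep(10, 5)))
  lum <- resample_isotropic(h$compartments, 2)
  cl <- central_line(lum, h$truth$inflow_point, h$truth$outflow_point)
  cv <- convolutedness(cl, h$truth$inflow_point, h$truth$outflow_point)
  expect_lt(abs(cv / ((pi / 2 * 50) / (50 * sqrt(2))) - 1), 0.05)
  expect_error(convolutedness(cl, c(1, 1, 1), c(1, 1, 1)), "coincident")
  expect_error(convolutedness(list(length = 0), c(0, 0, 0), c(1, 1, 1)), "positive")
})

test_that("convolutedness is invariant under rigid rotation of the volume", {
  h <- synthesize_heart(quiet_config(
    grid_shape = c(36, 100, 150), centerline_kind = "arc",
    centerline_params = list(radius = 50, turn_fraction = 0.5),
    tube_radius_by_compartment = rep(10, 5)))
  lum <- resample_isotropic(h$compartments, 2)
  cl <- central_line(lum, h$truth$inflow_point, h$truth$outflow_point)
  cv <- convolutedness(cl, h$truth$inflow_point, h$truth$outflow_point)

  # rotate the label volume 90 degrees in the (y, x) plane: y' = x, x' = ny - y
  arr <- unclass(lum)
  rot <- aperm(arr, c(1, 3, 2))[, , dim(arr)[2]:1]
  rot_lv <- label_volume(rot, spacing(lum))
  d2 <- dim(arr)
  rp <- function(p) c(p[1], p[3], d2[2] * spacing(lum)[2] - p[2])
  cl_r <- central_line(rot_lv, rp(h$truth$inflow_point), rp(h$truth$outflow_point))
  cv_r <- convolutedness(cl_r, rp(h$truth$inflow_point), rp(h$truth$outflow_point))
  expect_lt(abs(cv_r / cv - 1), 0.02)
})

test_that("measured convolutedness increases with the programmed turn fraction", {
  mk <- function(turn) {
    if (turn == 0)
      h <- synthesize_heart(quiet_config(
        grid_shape = c(36, 40, 200), centerline_kind = "straight",
        centerline_params = list(length = 157),
        tube_radius_by_compartment = rep(10, 5)))
    else
      h <- synthesize_heart(quiet_config(
        grid_shape = c(36, 130, 160), centerline_kind = "arc",
        centerline_params = list(radius = 157 / (2 * pi * turn), turn_fraction = turn),
        tube_radius_by_compartment = rep(10, 5)))
    lum <- resample_isotropic(h$compartments, 2)
    cl <- central_line(lum, h$truth$inflow_point, h$truth$outflow_point)
    convolutedness(cl, h$truth$inflow_point, h$truth$outflow_point)
  }
  cv <- c(mk(0), mk(0.25), mk(0.5))
  expect_true(all(diff(cv) > 0))
})

test_that("heart_morphometry runs end to end and respects its invariants", {
  h <- small_heart(seed = 17)
  m <- heart_morphometry(h$compartments)
  expect_s3_class(m, "morphometry_result")
  expect_gt(m$avc_length, 0)
  expect_gte(m$convolutedness, 1 - 0.01)
  expect_gte(m$central_line_length, m$straight_distance * (1 - 0.01))
  # depends only on labels: same result from a relabelled copy with noise
  # channels swapped out entirely
  m2 <- heart_morphometry(label_volume(unclass(h$compartments),
                                       spacing(h$compartments)))
  expect_equal(m2$avc_length, m$avc_length)
  expect_equal(m2$convolutedness, m$convolutedness)
})
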