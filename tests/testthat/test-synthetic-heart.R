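test_that("config validation aggregates errors and enforces invariants", {
  expect_error(synthetic_config(compartment_fractions = c(0.3, 0.3, 0.2, 0.1, 0.2)),
               "summing to 1")
  expect_error(synthetic_config(tube_radius_by_compartment = c(1, 2, -3, 4, 5)),
               "positive")
  err <- tryCatch(synthetic_config(spacing = c(0, 1, 1),
                                   psf_sigma = c(-1, 1, 1)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "spacing")
  expect_match(err, "psf_sigma")
  expect_error(synthetic_config(centerline_kind = "zigzag"), "unsupported")
})

test_that("make_centerline matches closed-form arc lengths", {
  # straight line, length 100
  cl <- make_centerline(quiet_config(grid_shape = c(48, 48, 180),
                                     centerline_kind = "straight",
                                     centerline_params = list(length = 100),
                                     tube_radius_by_compartment = rep(8, 5)))
  n <- length(cl$arclen)
  expect_equal(cl$arclen[n], 100, tolerance = 1e-6)
  chord <- sqrt(sum((cl$outflow - cl$inflow)^2))
  expect_equal(chord / cl$arclen[n], 1, tolerance = 1e-6)
  expect_true(all(diff(cl$arclen) > 0))

  # semicircular arc R = 50: arc length pi*R, endpoint separation 2R
  cl <- make_centerline(quiet_config(grid_shape = c(48, 100, 150),
                                     centerline_kind = "arc",
                                     centerline_params = list(radius = 50, turn_fraction = 0.5),
                                     tube_radius_by_compartment = rep(8, 5)))
  expect_equal(cl$arclen[length(cl$arclen)], pi * 50, tolerance = 1e-4)
  expect_equal(sqrt(sum((cl$outflow - cl$inflow)^2)), 100, tolerance = 1e-4)

  # helix arc length T*sqrt(R^2 + c^2) within 0.5%
  R <- 30; pitch <- 5; tmax <- 4 * pi
  cl <- make_centerline(quiet_config(grid_shape = c(120, 100, 100),
                                     centerline_kind = "helix",
                                     centerline_params = list(radius = R, pitch = pitch, t_max = tmax),
                                     tube_radius_by_compartment = rep(8, 5)))
  expect_equal(cl$arclen[length(cl$arclen)], tmax * sqrt(R^2 + pitch^2),
               tolerance = 5e-3)
})

test_that("centerline exiting the grid raises a geometry error naming the margin", {
  expect_error(
    make_centerline(quiet_config(grid_shape = c(20, 20, 60),
                                 centerline_kind = "straight",
                                 centerline_params = list(length = 100),
                                 tube_radius_by_compartment = rep(15, 5))),
    "margin")
})

test_that("lumen volume of a straight tube matches the analytic cylinder", {
  h <- synthesize_heart(quiet_config(
    grid_shape = c(60, 60, 160), centerline_kind = "straight",
    centerline_params = list(length = 100),
    tube_radius_by_compartment = rep(20, 5)))
  lum <- sum(unclass(h$compartments) > 0)
  expect_lt(abs(lum / (pi * 20^2 * 100) - 1), 0.03)
  # compartments partition the lumen: labels 1..5 inside, 0 outside
  expect_setequal(unique(as.vector(unclass(h$compartments))), 0:5)
})

test_that("a zero-noise zero-PSF spherical nucleus voxelizes to its analytic volume", {
  cfg <- quiet_config(grid_shape = c(48, 48, 120), centerline_kind = "straight",
                      centerline_params = list(length = 60),
                      compartment_fractions = c(0.1, 0.2, 0.4, 0.2, 0.1),
                      tube_radius_by_compartment = rep(12, 5))
  cfg$n_nuclei_by_compartment <- c(0L, 0L, 1L, 0L, 0L)
  cfg$nucleus_axes_mean <- c(5, 5, 5)
  cfg$nucleus_axes_sd <- 0
  h <- synthesize_heart(cfg)
  cnt <- sum(unclass(h$nuclei_true) > 0)
  expect_lt(abs(cnt / (4 / 3 * pi * 125) - 1), 0.05)
  expect_equal(h$truth$nuclei$volume_um3, 4 / 3 * pi * 125, tolerance = 1e-9)
})

test_that("seeding contract: same seed bit-identical, different seed differs", {
  cfg <- synthetic_config(grid_shape = c(32, 80, 120),
                          tube_radius_by_compartment = c(8, 10, 6, 11, 8),
                          centerline_params = list(radius = 40, turn_fraction = 0.5),
                          n_nuclei_by_compartment = c(1, 3, 2, 3, 1), seed = 7)
  h1 <- synthesize_heart(cfg)
  h2 <- synthesize_heart(cfg)
  expect_identical(as.vector(h1$nuclear), as.vector(h2$nuclear))
  expect_identical(as.vector(h1$membrane), as.vector(h2$membrane))
  expect_identical(h1$truth$nuclei, h2$truth$nuclei)
  cfg$seed <- 8L
  h3 <- synthesize_heart(cfg)
  expect_false(identical(as.vector(h1$nuclear), as.vector(h3$nuclear)))
})

test_that("ground-truth invariants hold on a generated heart", {
  h <- small_heart(seed = 3)
  tr <- h$truth
  # every nucleus lies in its compartment's arc-length interval
  iv <- tr$compartment_intervals
  for (i in seq_len(nrow(tr$nuclei))) {
    row <- iv[iv$compartment == tr$nuclei$compartment[i], ]
    expect_gte(tr$nuclei$arclen[i], row$arclen_lo)
    expect_lte(tr$nuclei$arclen[i], row$arclen_hi)
  }
  expect_gte(tr$analytic_convolutedness, 1)
  expect_true(all(tr$nuclei$volume_um3 > 0))
  # nucleus instances are disjoint by construction (labels count each voxel once)
  labs <- unclass(h$nuclei_true)
  expect_equal(sort(unique(labs[labs > 0])), seq_len(nrow(tr$nuclei)))
})

test_that("noise-free blurred ellipsoid conserves integrated intensity within 1%", {
  cfg <- quiet_config(grid_shape = c(48, 48, 120), centerline_kind = "straight",
                      centerline_params = list(length = 60),
                      compartment_fractions = c(0.1, 0.2, 0.4, 0.2, 0.1),
                      tube_radius_by_compartment = rep(12, 5))
  cfg$n_nuclei_by_compartment <- c(0L, 0L, 1L, 0L, 0L)
  cfg$psf_sigma <- c(1.2, 0.6, 0.6)
  cfg$background <- 0
  h <- synthesize_heart(cfg)
  n_vox <- sum(unclass(h$nuclei_true) > 0)
  integral <- sum(h$nuclear)
  expect_lt(abs(integral / (cfg$nuclear_intensity * n_vox) - 1), 0.01)
})

test_that("overcrowded compartments fail with an informative placement error", {
  cfg <- quiet_config(grid_shape = c(48, 48, 120), centerline_kind = "straight",
                      centerline_params = list(length = 60),
                      tube_radius_by_compartment = rep(10, 5))
  cfg$n_nuclei_by_compartment <- c(0L, 0L, 500L, 0L, 0L)
  expect_error(synthesize_heart(cfg), "AVC")
})

test_that("written heart round-trips through TIFF + CSV", {
  dir <- withr::local_tempdir()
  h <- small_heart(seed = 11)
  write_synthetic_heart(h, dir)
  img <- read_tiff(file.path(dir, "nuclear.tif"))
  expect_equal(dim(img), dim(h$nuclear))
  expect_equal(as.vector(img), as.vector(h$nuclear), tolerance = 1e-6)
  lab <- read_tiff(file.path(dir, "compartments.tif"))
  expect_identical(as.vector(unclass(lab)), as.vector(unclass(h$compartments)))
  nuc <- read.csv(file.path(dir, "nuclei_true.csv"))
  expect_equal(nrow(nuc), nrow(h$truth$nuclei))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(gt$analytic_convolutedness, h$truth$analytic_convolutedness)
})
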