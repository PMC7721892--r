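# Rotation, monotonic resampling, baseline normalization, sign convention and
# the curvature-angle statistic.

test_that("curvature_angle matches the brute-force oracle on the fixture", {
  grid <- c(0, 2.5, 5, 7.5, 10)
  ortho <- c(0, 0.5, 1, 0.5, 0)
  expected <- oracle_curvature(grid, ortho) # median of 11.31, 11.31, 3.81
  got <- curvature_angle(data.frame(grid = grid, ortho = ortho))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(round(got, 2), 11.31)
  # all points on the chord
  expect_identical(curvature_angle(data.frame(grid = grid, ortho = 0)), 0)
  # odd symmetry
  expect_equal(curvature_angle(data.frame(grid = grid, ortho = -ortho)),
               -expected, tolerance = 1e-12)
})

test_that("curvature_angle respects the interior margin and degeneracies", {
  # points inside the 5% margin are excluded from the median
  grid <- c(0, 0.2, 2.5, 5, 7.5, 9.9, 10)
  ortho <- c(0, 5, 0.5, 1, 0.5, -5, 0)
  expect_equal(curvature_angle(data.frame(grid = grid, ortho = ortho)),
               oracle_curvature(grid, ortho), tolerance = 1e-12)
  expect_error(curvature_angle(data.frame(grid = rep(0, 5),
                                          ortho = rep(0, 5))),
               "degenerate")
  expect_error(curvature_angle(data.frame(grid = 0:3, ortho = 0)),
               "at least 5")
})

test_that("curvature is invariant under rigid motions of the scene", {
  p <- curved_saccade_path(c(0, 0), c(0, 15), 4, duration = 60)
  base <- saccurv:::path_curvature(p)
  set.seed(42)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    shift <- runif(2, -20, 20)
    q <- data.frame(
      t_ms = p$t_ms,
      x_deg = cos(th) * p$x_deg - sin(th) * p$y_deg + shift[1],
      y_deg = sin(th) * p$x_deg + cos(th) * p$y_deg + shift[2]
    )
    expect_equal(saccurv:::path_curvature(q), base, tolerance = 1e-9)
  }
})

test_that("rotate_to_upward is the identity for an already-upward saccade", {
  t <- 0:54
  s <- saccurv:::raised_cosine_progress(t / 54)
  trace <- data.frame(t_ms = t + 480, x_deg = 0.3 * sin(pi * s),
                      y_deg = s * 15)
  second <- list(onset_t = 480, offset_t = 534, x0 = 0, y0 = 0)
  rot <- rotate_to_upward(second, trace, list(target2_dir = "up"))
  expect_equal(rot$along, trace$y_deg, tolerance = 1e-12)
  expect_equal(rot$ortho, trace$x_deg, tolerance = 1e-12) # right normal = +x
  # down-saccade: along still increases over time
  trace_d <- data.frame(t_ms = t + 480, x_deg = 0, y_deg = -s * 15)
  rot_d <- rotate_to_upward(list(onset_t = 480, offset_t = 534, x0 = 0,
                                 y0 = 0),
                            trace_d, list(target2_dir = "down"))
  expect_true(all(diff(rot_d$along) >= -1e-12))
  expect_error(rotate_to_upward(list(onset_t = 480, offset_t = 482, x0 = 0,
                                     y0 = 0),
                                trace, list(target2_dir = "up")),
               "fewer than 5")
})

test_that("monotonic_resample handles straight, bumped and overshooting paths", {
  # straight path -> zero profile
  rot <- data.frame(along = seq(0, 15, length.out = 60), ortho = 0)
  prof <- monotonic_resample(rot)
  expect_true(all(prof$ortho == 0))
  expect_true(all(diff(prof$grid) > 0))

  # sine bump reproduced within bin quantization
  along <- seq(0, 15, length.out = 400)
  bump <- data.frame(along = along, ortho = 0.8 * sin(pi * along / 15))
  prof <- monotonic_resample(bump)
  expect_lt(max(abs(prof$ortho - 0.8 * sin(pi * prof$grid / 15))), 0.01)

  # dynamic overshoot: along doubles back, grid stays strictly monotonic
  over <- data.frame(along = c(seq(0, 15.6, length.out = 50),
                               seq(15.6, 15, length.out = 10)),
                     ortho = 0.2)
  prof <- monotonic_resample(over, amplitude = 15)
  expect_true(all(diff(prof$grid) > 0))

  expect_error(monotonic_resample(rot, amplitude = -1), "strictly positive")
  expect_error(monotonic_resample(rot[1:5, ], n_bins = 50), "too few")
})

test_that("baseline normalization removes shared structure", {
  grid <- (1:50 - 0.5) * 15 / 50
  bump <- sin(pi * grid / 15)
  prof <- structure(data.frame(grid = grid, ortho = bump + 0.3),
                    class = c("monotonic_profile", "data.frame"))
  base <- structure(data.frame(grid = grid, ortho = rep(0.3, 50)),
                    class = c("monotonic_profile", "data.frame"))
  norm <- normalize_trajectory(prof, base)
  expect_equal(norm$ortho, bump, tolerance = 1e-12)
  # trial equal to its baseline -> identically zero
  norm0 <- normalize_trajectory(prof, prof)
  expect_true(all(norm0$ortho == 0))
  # mismatched grids are re-gridded rather than rejected
  base2 <- data.frame(grid = seq(0.1, 14.9, length.out = 30), ortho = 0.3)
  norm2 <- normalize_trajectory(prof, base2)
  expect_equal(norm2$ortho, bump, tolerance = 1e-9)
  # thin baselines carry a warning flag
  attr(base, "n_trials") <- 3
  expect_true(attr(normalize_trajectory(prof, base), "baseline_warning"))
})

test_that("sign convention makes mirrored physics identical", {
  grid <- (1:50 - 0.5) * 15 / 50
  traj <- data.frame(grid = grid, ortho = 0.6 * sin(pi * grid / 15))
  cw <- apply_sign_convention(traj, "clockwise")
  expect_identical(cw$ortho, traj$ortho)
  ccw <- apply_sign_convention(traj, "counterclockwise")
  expect_identical(ccw$ortho, -traj$ortho)

  # mirrored pair: same physics relative to the distractor, opposite
  # rotation; identical signed curvature after the convention
  toward_cw <- curvature_angle(apply_sign_convention(traj, "clockwise"))
  mirrored <- data.frame(grid = grid, ortho = -traj$ortho)
  toward_ccw <- curvature_angle(apply_sign_convention(mirrored,
                                                      "counterclockwise"))
  expect_equal(toward_cw, toward_ccw, tolerance = 1e-12)
})
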