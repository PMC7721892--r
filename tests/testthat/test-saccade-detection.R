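# Velocity computation, threshold detection and double-step sequence
# assignment.

test_that("compute_velocity reproduces known speeds", {
  t <- 0:199
  # stationary trace -> zero speed everywhere it is defined
  still <- data.frame(t_ms = t, x_deg = 3, y_deg = -2)
  v <- compute_velocity(still)
  expect_true(all(v$v[!is.na(v$v)] == 0))

  # constant drift of 10 deg/s -> smoothed speed 10 after the margin
  drift <- data.frame(t_ms = t, x_deg = 0.010 * t, y_deg = 0)
  v <- compute_velocity(drift)
  expect_equal(v$v[!is.na(v$v)], rep(10, sum(!is.na(v$v))), tolerance = 1e-9)

  # smoothing is averaging: smoothed peak cannot exceed the raw peak
  p <- curved_saccade_path(c(-15, 0), c(0, 0), 0, duration = 54)
  pad <- data.frame(t_ms = c(-100:-1, p$t_ms, 55:154),
                    x_deg = c(rep(-15, 100), p$x_deg, rep(0, 100)),
                    y_deg = 0)
  raw <- max(abs(diff(pad$x_deg)) / diff(pad$t_ms) * 1000)
  v <- compute_velocity(pad)
  expect_lte(max(v$v, na.rm = TRUE), raw + 1e-9)
})

test_that("compute_velocity validates its input", {
  expect_error(
    compute_velocity(data.frame(t_ms = c(0, 1, 3, 4, 6), x_deg = 0,
                                y_deg = 0)[rep(1:5, 10), ]),
    "uniform"
  )
  expect_error(
    compute_velocity(data.frame(t_ms = 0:5, x_deg = 0, y_deg = 0)),
    "too short"
  )
})

test_that("detection requires a sustained threshold crossing", {
  # fixation-only noiseless trace: nothing crosses
  still <- data.frame(t_ms = 0:299, x_deg = 15, y_deg = 0)
  v <- compute_velocity(still)
  expect_identical(nrow(detect_saccades(v, trace = still)), 0L)

  # hand-built velocity traces around a flat baseline: a 15 ms burst is
  # rejected, a 25 ms burst of the same height is kept
  mkvel <- function(run_len) {
    v <- rep(1, 400)
    v[200:(199 + run_len)] <- 300
    out <- data.frame(t_ms = seq_len(400) - 1, v = v)
    attr(out, "dt_ms") <- 1
    out
  }
  expect_identical(nrow(detect_saccades(mkvel(15))), 0L)
  s <- detect_saccades(mkvel(25))
  expect_identical(nrow(s), 1L)
  expect_identical(s$onset_t, 199)

  expect_error(
    detect_saccades(structure(data.frame(t_ms = 0:99, v = NA_real_),
                              dt_ms = 1)),
    "undefined"
  )
})

test_that("noiseless onsets match ground truth within 2 ms", {
  sim <- simulate_experiment(clean_sim_config(idiosyncrasy_sd = 1,
                                              trial_curvature_sd = 1.5))
  gaze <- as.data.frame(sim$gaze)
  ids <- sim$events$trial_id[1:20]
  app <- sim$config$apparatus
  for (id in ids) {
    tr <- gaze[gaze$trial_id == id, ]
    s <- detect_saccades(compute_velocity(tr), trace = tr)
    ev <- as.list(sim$events[sim$events$trial_id == id, ])
    a <- assign_sequence(s, ev, app)
    expect_true(a$valid)
    truth <- sim$truth[sim$truth$trial_id == id, ]
    expect_lte(abs(a$first$onset_t - truth$on1_true), 2)
    expect_lte(abs(a$second$onset_t - truth$on2_true), 2)
  }
})

test_that("noisy onsets have a median absolute error under 5 ms", {
  sim <- simulate_experiment(clean_sim_config(noise_sd = 0.05,
                                              idiosyncrasy_sd = 1,
                                              trial_curvature_sd = 1.5))
  gaze <- as.data.frame(sim$gaze)
  errs <- c()
  for (id in sim$events$trial_id[1:60]) {
    tr <- gaze[gaze$trial_id == id, ]
    s <- detect_saccades(compute_velocity(tr), trace = tr)
    ev <- as.list(sim$events[sim$events$trial_id == id, ])
    a <- assign_sequence(s, ev, sim$config$apparatus)
    if (!a$valid) next
    truth <- sim$truth[sim$truth$trial_id == id, ]
    errs <- c(errs, a$first$onset_t - truth$on1_true,
              a$second$onset_t - truth$on2_true)
  }
  expect_gt(length(errs), 100)
  expect_lte(median(abs(errs)), 5)
})

test_that("raising the threshold multiplier never adds saccades", {
  sim <- simulate_experiment(small_sim_config())
  gaze <- as.data.frame(sim$gaze)
  tr <- gaze[gaze$trial_id == sim$events$trial_id[1], ]
  counts <- vapply(c(2, 3, 4, 6, 10), function(k) {
    par <- detection_params(k = k)
    nrow(detect_saccades(compute_velocity(tr, par), par, trace = tr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("assign_sequence resolves the double-step structure", {
  ev <- make_events(fixation_side = "right")
  app <- apparatus_config()

  # clean pair
  s <- rbind(make_saccade(170, 225, 15, 0, 0.1, 0),
             make_saccade(480, 534, 0.1, 0, 0, 15))
  a <- assign_sequence(s, ev, app)
  expect_true(a$valid)
  expect_equal(a$first$onset_t, 170)
  expect_equal(a$second$onset_t, 480)

  # diagonal saccade straight to the second target: no center saccade
  s <- rbind(make_saccade(200, 260, 15, 0, 0.2, 15),
             make_saccade(400, 425, 0.2, 15, 0, 15))
  expect_false(assign_sequence(s, ev, app)$valid)
  expect_identical(assign_sequence(s, ev, app)$reason,
                   "missing_center_saccade")

  # small corrective movement after the first saccade is ignored
  s <- rbind(make_saccade(170, 225, 15, 0, 1.2, 0.5),
             make_saccade(260, 282, 1.2, 0.5, 0.1, 0),
             make_saccade(480, 534, 0.1, 0, 0, 15))
  a <- assign_sequence(s, ev, app)
  expect_true(a$valid)
  expect_equal(a$first$onset_t, 170)
  expect_equal(a$second$onset_t, 480)

  # fewer than two saccades
  expect_identical(assign_sequence(s[1, ], ev, app)$reason,
                   "too_few_saccades")
})
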