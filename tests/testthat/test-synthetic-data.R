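# Synthetic-data generator: path construction, per-trial simulation, and the
# seeded experiment builder.

test_that("curved_saccade_path hits the requested curvature statistic", {
  # straight path: all samples collinear with the start->end line
  p0 <- curved_saccade_path(c(3, 2), c(-7, 9), 0, duration = 54)
  expect_lt(abs(saccurv:::path_curvature(p0)), 1e-9)
  # generator/statistic consistency across the calibrated range
  for (c_deg in seq(-10, 10, by = 2.5)) {
    if (c_deg == 0) next
    p <- curved_saccade_path(c(0, 0), c(0, 15), c_deg, duration = 60)
    expect_lt(abs(saccurv:::path_curvature(p) - c_deg), 0.05)
  }
  # reflection symmetry
  p_pos <- curved_saccade_path(c(0, 0), c(0, 15), 5, duration = 60)
  p_neg <- curved_saccade_path(c(0, 0), c(0, 15), -5, duration = 60)
  expect_equal(saccurv:::path_curvature(p_neg),
               -saccurv:::path_curvature(p_pos), tolerance = 1e-9)
})

test_that("curved_saccade_path endpoints are exact and progress is monotonic", {
  p <- curved_saccade_path(c(-15, 0), c(0, 0), 4, duration = 54)
  expect_equal(unlist(p[1, c("x_deg", "y_deg")], use.names = FALSE),
               c(-15, 0), tolerance = 1e-12)
  expect_equal(unlist(p[nrow(p), c("x_deg", "y_deg")], use.names = FALSE),
               c(0, 0), tolerance = 1e-12)
  # along-axis progress never reverses
  along <- (p$x_deg + 15) # direction (1, 0)
  expect_true(all(diff(along) >= -1e-12))
})

test_that("curved_saccade_path rejects degenerate requests", {
  expect_error(curved_saccade_path(c(0, 0), c(0, 0), 2, 50), "zero-amplitude")
  expect_error(curved_saccade_path(c(0, 0), c(0, 15), 2, 5), "at least 10 ms")
})

test_that("noiseless trials carry exactly the composed curvature", {
  cfg <- clean_sim_config()
  set.seed(42)
  tr <- simulate_trial(make_events(modality = "none"), config = cfg)
  truth <- tr$truth
  sel <- tr$trace$t_ms >= truth$on2_true & tr$trace$t_ms <= truth$off2_true
  curv <- saccurv:::path_curvature(tr$trace[sel, ])
  # zero noise, zero effects, zero idiosyncrasy, zero jitter -> straight
  expect_lt(abs(curv), 1e-9)

  # injected components compose to the realized curvature (heights add;
  # the statistic is close to additive over the tested range)
  cfg2 <- clean_sim_config(idiosyncrasy_sd = 1, trial_curvature_sd = 1.5)
  set.seed(7)
  for (i in 1:5) {
    tr <- simulate_trial(
      make_events(modality = "visual", d_onset = 150),
      participant_params = list(idiosyncrasy_deg = 0.8),
      config = cfg2
    )
    truth <- tr$truth
    sel <- tr$trace$t_ms >= truth$on2_true & tr$trace$t_ms <= truth$off2_true
    curv <- saccurv:::path_curvature(tr$trace[sel, ])
    eff_frame <- truth$effect_curvature_deg
    if (!is.na(tr$events$distractor_x_deg)) {
      rot <- distractor_rotation(tr$events)
      if (rot == "counterclockwise") eff_frame <- -eff_frame
    }
    injected <- truth$baseline_curvature_deg + truth$trial_jitter_deg +
      eff_frame
    expect_lt(abs(curv - injected), 0.05)
  }
})

test_that("forced blinks always produce a missing-sample gap", {
  cfg <- clean_sim_config(
    artifact_rates = list(blink = 1, fixation_break = 0, landing_error = 0)
  )
  set.seed(42)
  for (i in 1:3) {
    tr <- simulate_trial(make_events(), config = cfg)
    expect_true(anyNA(tr$trace$x_deg))
    expect_true(tr$truth$blink)
  }
})

test_that("simulate_experiment is deterministic and balanced", {
  cfg <- small_sim_config()
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$gaze, sim2$gaze)
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim1$truth, sim2$truth)

  # closed-form row count: artifacts only flag, never drop rows
  n_expected <- as.integer(
    cfg$n_participants *
      (3 * 2 * 4 * cfg$trials_per_cell + 4 * cfg$baseline_trials_per_cell)
  )
  expect_identical(nrow(sim1$events), n_expected)
  expect_identical(nrow(sim1$truth), n_expected)
  expect_setequal(sim1$gaze$trial_id, sim1$events$trial_id)
  expect_identical(sim1$truth$trial_id, sim1$events$trial_id)

  # every ground-truth record is internally consistent
  expect_true(all(sim1$truth$on1_true < sim1$truth$off1_true))
  expect_true(all(sim1$truth$on2_true < sim1$truth$off2_true))
  expect_true(all(sim1$truth$off1_true < sim1$truth$on2_true))
})

test_that("distractor onsets stay within the configured range", {
  cfg <- small_sim_config()
  sim <- simulate_experiment(cfg)
  on <- sim$events$distractor_onset_ms
  expect_true(all(is.na(on) | (on >= -100 & on <= 300)))
  # distractor-present trials populate both timing windows
  expect_true(any(sim$truth$interval_true == "pre_saccadic"))
  expect_true(any(sim$truth$interval_true == "inter_saccadic"))
})

test_that("straight-saccade curvature is unbiased under isotropic noise", {
  # noise neutrality: >= 500 straight second saccades, mean recovered
  # curvature within 3 standard errors of 0
  cfg <- clean_sim_config(noise_sd = 0.05)
  t <- 0:54
  s <- saccurv:::raised_cosine_progress(t / 54)
  set.seed(42)
  vals <- vapply(1:500, function(i) {
    tr <- data.frame(t_ms = t,
                     x_deg = rnorm(55, 0, 0.05),
                     y_deg = s * 15 + rnorm(55, 0, 0.05))
    saccurv:::path_curvature(tr)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulation_config(n_participants = 0), "strictly positive")
  expect_error(simulation_config(trials_per_cell = -1), "strictly positive")
  expect_error(apparatus_config(sampling_rate = 100), "250")
})
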