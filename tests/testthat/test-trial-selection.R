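# Inclusion filters, distractor-interval windows, hemifield taxonomy,
# eccentricity and rotation.

test_that("validate_trial reports the first failing criterion", {
  ev <- make_events()
  crit <- selection_criteria()
  first <- make_saccade(170, 225, 15, 0, 0.1, 0)
  second <- make_saccade(480, 534, 0.1, 0, 0, 15)

  expect_true(validate_trial(ev, first, second, crit)$valid)

  # first saccade lands 3.6 deg from the center target
  bad <- make_saccade(170, 225, 15, 0, 3.6, 0)
  v <- validate_trial(ev, bad, second, crit)
  expect_false(v$valid)
  expect_identical(v$reason, "first_landing_error")
  # exactly at the radius is still valid
  edge <- make_saccade(170, 225, 15, 0, 3.5, 0)
  expect_true(validate_trial(ev, edge, second, crit)$valid)

  # late first saccade (cap 400 ms)
  late <- make_saccade(420, 475, 15, 0, 0.1, 0)
  v <- validate_trial(ev, late, second, crit)
  expect_identical(v$reason, "late_first_saccade")

  # blink dominates other failures
  v <- validate_trial(ev, late, second, crit, has_blink = TRUE)
  expect_identical(v$reason, "blink")

  # fixation break detected from the trace
  trace <- data.frame(t_ms = -250:100, x_deg = 15, y_deg = 0)
  trace$y_deg[trace$t_ms %in% -150:-100] <- 6
  v <- validate_trial(ev, first, second, crit, trace = trace)
  expect_identical(v$reason, "fixation_break")

  # second saccade landing off the second target
  bad2 <- make_saccade(480, 534, 0.1, 0, 0, 10.9)
  v <- validate_trial(ev, first, bad2, crit)
  expect_identical(v$reason, "second_landing_error")
})

test_that("distractor interval windows have exact boundaries", {
  crit <- selection_criteria()
  first <- make_saccade(200, 254, 15, 0, 0, 0)
  second <- make_saccade(600, 654, 0, 0, 0, 15)
  cls <- function(onset, dur = 50) {
    classify_distractor_interval(make_events(d_onset = onset, d_duration = dur),
                                 first, second, crit)
  }
  # pre-saccadic window: offset in [onset1 - 150, onset1)
  expect_identical(cls(200 - 150 - 50), "pre_saccadic")      # offset = on1-150
  expect_identical(cls(200 - 151 - 50), "excluded")          # 1 ms earlier
  expect_identical(cls(200 - 1 - 50), "pre_saccadic")        # offset = on1-1
  expect_identical(cls(200 - 50), "excluded")                # offset = on1
  # inter-saccadic window: onset > offset1, offset <= onset2 - 100
  expect_identical(cls(254), "excluded")                     # onset = off1
  expect_identical(cls(255), "inter_saccadic")               # onset = off1+1
  expect_identical(cls(600 - 100 - 50), "inter_saccadic")    # offset = on2-100
  expect_identical(cls(600 - 99 - 50), "excluded")           # offset = on2-99
  # canonical cases
  expect_identical(cls(200 - 120 - 50), "pre_saccadic")
  expect_identical(cls(264, dur = 600 - 150 - 264), "inter_saccadic")
  expect_identical(cls(600 - 50 - 50), "excluded")
  expect_identical(cls(200 - 200 - 50), "excluded")

  expect_identical(
    classify_distractor_interval(make_events(modality = "none"),
                                 first, second, crit),
    "no_distractor"
  )
  expect_error(cls(100, dur = -5), "malformed")
})

test_that("every distractor timing maps to exactly one interval label", {
  crit <- selection_criteria()
  first <- make_saccade(200, 254, 15, 0, 0, 0)
  second <- make_saccade(600, 654, 0, 0, 0, 15)
  labels <- vapply(seq(-100, 560, length.out = 1000), function(onset) {
    classify_distractor_interval(make_events(d_onset = round(onset)),
                                 first, second, crit)
  }, character(1))
  expect_true(all(labels %in% c("pre_saccadic", "inter_saccadic", "excluded")))
  # moving the distractor later flips the label exactly at the boundaries:
  # pre starts, pre ends, inter starts, inter ends
  flips <- sum(labels[-1] != labels[-length(labels)])
  expect_identical(flips, 4L)
})

test_that("hemifield classification follows the fixation side", {
  app <- apparatus_config()
  expect_identical(
    classify_hemifield(make_events("right", d_x = 7.5, d_y = 7.5), app),
    "inter"
  )
  expect_identical(
    classify_hemifield(make_events("right", d_x = -7.5, d_y = 7.5), app),
    "intra"
  )
  # mirror symmetry
  expect_identical(
    classify_hemifield(make_events("left", d_x = -7.5, d_y = -7.5), app),
    "inter"
  )
  expect_identical(
    classify_hemifield(make_events("left", d_x = 7.5, d_y = -7.5), app),
    "intra"
  )
  expect_error(classify_hemifield(make_events(d_x = 0), app), "midline")
})

test_that("eye-distractor eccentricity matches the geometry", {
  expect_equal(eye_distractor_eccentricity(c(15, 0), c(7.5, 7.5)),
               sqrt(7.5^2 + 7.5^2), tolerance = 1e-12)
  expect_equal(round(eye_distractor_eccentricity(c(15, 0), c(7.5, 7.5)), 2),
               10.61)
  expect_equal(round(eye_distractor_eccentricity(c(15, 0), c(-7.5, 7.5)), 2),
               23.72)
  expect_identical(eye_distractor_eccentricity(c(15, 0), c(15, 0)), 0)
  # the flat-screen angular separation is close to, but distinct from, the
  # planar distance
  ang <- eye_distractor_eccentricity(c(15, 0), c(-7.5, 7.5),
                                     method = "angular")
  expect_lt(abs(ang - 23.6), 0.2)
})

test_that("distractor rotation matches a signed-angle oracle", {
  # brute-force oracle: signed angle from the target direction to the
  # distractor direction about the screen center
  oracle <- function(t2, d) {
    tv <- c(0, if (t2 == "up") 1 else -1)
    ang <- atan2(tv[1] * d[2] - tv[2] * d[1], tv[1] * d[1] + tv[2] * d[2])
    if (ang < 0) "clockwise" else "counterclockwise"
  }
  for (t2 in c("up", "down")) {
    for (corner in list(c(7.5, 7.5), c(-7.5, 7.5), c(-7.5, -7.5),
                        c(7.5, -7.5))) {
      ev <- make_events(target2_dir = t2, d_x = corner[1], d_y = corner[2])
      expect_identical(distractor_rotation(ev), oracle(t2, corner))
    }
  }
  # canonical cases
  expect_identical(distractor_rotation(make_events(target2_dir = "up",
                                                   d_x = 7.5, d_y = 7.5)),
                   "clockwise")
  expect_identical(distractor_rotation(make_events(target2_dir = "up",
                                                   d_x = -7.5, d_y = 7.5)),
                   "counterclockwise")
  expect_identical(distractor_rotation(make_events(target2_dir = "down",
                                                   d_x = -7.5, d_y = -7.5)),
                   "clockwise")
  expect_error(distractor_rotation(make_events(d_x = 0, d_y = 7.5)),
               "collinear")
})
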