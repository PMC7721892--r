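# Shared fixtures and independent oracles for the test suite.

# Small, fast experiment configurations ---------------------------------------

# noiseless, artifact-free configuration for detection-accuracy checks;
# overrides win over the defaults below
clean_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2, trials_per_cell = 4,
         baseline_trials_per_cell = 8,
         noise_sd = 0, trial_curvature_sd = 0, idiosyncrasy_sd = 0,
         artifact_rates = list(blink = 0, fixation_break = 0,
                               landing_error = 0),
         seed = 42),
    list(...)
  )
  do.call(simulation_config, args)
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2, trials_per_cell = 3,
         baseline_trials_per_cell = 6, seed = 42),
    list(...)
  )
  do.call(simulation_config, args)
}

zero_effect_map <- function() {
  em <- default_effect_map()
  em$curvature_deg <- 0
  em
}

# Independent oracles ----------------------------------------------------------

# brute-force curvature oracle: per-point arctangent from the chord of the
# (grid, ortho) point set, then the median over points strictly inside the
# margin. Written directly from the definition, independent of the package's
# vectorized implementation.
oracle_curvature <- function(grid, ortho, margin = 0.05) {
  n <- length(grid)
  p1 <- c(grid[1], ortho[1])
  p2 <- c(grid[n], ortho[n])
  chord <- p2 - p1
  len <- sqrt(sum(chord^2))
  angs <- c()
  for (i in 2:(n - 1)) {
    rel <- c(grid[i], ortho[i]) - p1
    a <- sum(rel * chord) / len
    d <- (rel[2] * chord[1] - rel[1] * chord[2]) / len
    if (a / len > margin && a / len < 1 - margin) {
      angs <- c(angs, atan2(d, a) * 180 / pi)
    }
  }
  median(angs)
}

# one-row events helper
make_events <- function(fixation_side = "right", target2_dir = "up",
                        modality = "visual", d_x = 7.5, d_y = 7.5,
                        d_onset = 250, d_duration = 50, trial_id = 1L,
                        participant = 1L) {
  list(
    trial_id = trial_id, participant = participant,
    fixation_side = fixation_side, target2_dir = target2_dir,
    distractor_modality = modality,
    distractor_x_deg = if (modality == "none") NA_real_ else d_x,
    distractor_y_deg = if (modality == "none") NA_real_ else d_y,
    distractor_onset_ms = if (modality == "none") NA_real_ else d_onset,
    distractor_duration_ms = if (modality == "none") NA_real_ else d_duration
  )
}

# one-row saccade helper
make_saccade <- function(onset, offset, x0, y0, x1, y1) {
  data.frame(
    onset_t = onset, offset_t = offset, duration = offset - onset,
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    amplitude = sqrt((x1 - x0)^2 + (y1 - y0)^2),
    peak_v = 400, latency = onset
  )
}
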