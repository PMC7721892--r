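# Synthetic double-step saccade experiment generator.
#
# Each trial: fixation 15 deg left/right of center -> first horizontal saccade
# to screen center -> second vertical saccade to a target 15 deg above/below
# center. Saccades follow raised-cosine speed profiles; the second saccade
# carries orthogonal curvature composed additively of a per-participant,
# per-sequence idiosyncratic bump, a trial-to-trial jitter bump and (when the
# distractor falls in a pre- or inter-saccadic window) a distractor-evoked
# bump of configurable curvature angle. Isotropic Gaussian noise is added
# after path construction. Artifacts (blinks, fixation breaks, inaccurate
# first-saccade landings) are injected at configurable rates to exercise the
# selection filters.

# internal: vectorized truncated-normal sampling (inverse-CDF; draws exactly
# one uniform per value, keeping the draw count seed-stable)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

# internal: distractor position given second-target direction and rotation
# (clockwise = rotated -45 deg from the target direction about screen center)
.distractor_xy <- function(target2_dir, rotation, offset) {
  up <- target2_dir == "up"
  cw <- rotation == "clockwise"
  x <- ifelse(up == cw, offset, -offset)
  y <- ifelse(up, offset, -offset)
  cbind(x_deg = x, y_deg = y)
}

# internal: realized distractor interval from true saccade times (same
# windows as the offline classifier: a pre-saccadic distractor ends within
# pre_window ms before first-saccade onset; an inter-saccadic distractor
# starts after first-saccade offset and ends at least inter_gap ms before
# second-saccade onset)
.realized_interval <- function(d_on, d_off, on1, off1, on2,
                               pre_window = 150, inter_gap = 100) {
  out <- rep("excluded", length(d_on))
  out[is.na(d_on)] <- "no_distractor"
  pre <- !is.na(d_on) & d_off >= on1 - pre_window & d_off < on1
  inter <- !is.na(d_on) & d_on > off1 & d_off <= on2 - inter_gap
  out[pre] <- "pre_saccadic"
  out[inter] <- "inter_saccadic"
  out
}

# internal: look up the injected effect for (modality, realized interval,
# hemifield) in the effect map; zero for excluded / distractor-absent trials
.effect_lookup <- function(effect_map, modality, interval, hemifield) {
  key <- function(m, i, h) paste(m, i, h, sep = "\r")
  map_h <- ifelse(effect_map$interval == "inter_saccadic", "any",
                  effect_map$hemifield)
  tab <- stats::setNames(effect_map$curvature_deg,
                         key(effect_map$modality, effect_map$interval, map_h))
  h <- ifelse(interval == "inter_saccadic", "any", hemifield)
  val <- tab[key(modality, interval, h)]
  val[is.na(val)] <- 0
  unname(val)
}

# internal: per-trial dynamics (latencies, durations, curvature components,
# artifacts). `trials` needs columns: participant, fixation_side, target2_dir,
# modality, lat1_shift, lat2_shift, idio_deg. Draw order is fixed so a given
# seed yields identical tables.
.draw_dynamics <- function(trials, config) {
  n <- nrow(trials)
  app <- config$apparatus
  lm <- config$latency_model
  ecc <- app$target_eccentricity
  dur1 <- round(config$duration_slope * ecc + config$duration_intercept)
  dur2 <- dur1

  mu1 <- lm$first[trials$modality] + trials$lat1_shift
  trials$on1 <- round(rtrunc_norm(n, mu1, lm$trial_sd_first, 80, 380))
  trials$dur1 <- dur1
  trials$off1 <- trials$on1 + dur1

  mu2 <- lm$second[trials$modality] + trials$lat2_shift
  trials$on2 <- round(rtrunc_norm(n, mu2, lm$trial_sd_second,
                                  trials$off1 + 150, 690))
  trials$dur2 <- dur2
  trials$off2 <- trials$on2 + dur2

  trials$jit_deg <- stats::rnorm(n, 0, config$trial_curvature_sd)

  rates <- config$artifact_rates
  trials$blink <- stats::runif(n) < rates$blink
  trials$fixation_break <- stats::runif(n) < rates$fixation_break
  trials$landing_error <- stats::runif(n) < rates$landing_error
  trials$blink_start <- round(stats::runif(n, -100, trials$on2))
  trials$fb_start <- round(stats::runif(n, -200, -110))
  land_mag <- stats::runif(n, app$fixation_radius + 0.5,
                           app$fixation_radius + 2)
  land_ang <- stats::runif(n, 0, 2 * pi)
  trials$land1_x <- ifelse(trials$landing_error, land_mag * cos(land_ang), 0)
  trials$land1_y <- ifelse(trials$landing_error, land_mag * sin(land_ang), 0)
  trials
}

# internal: distractor geometry/timing realization and curvature composition.
# `trials` must already carry dynamics and, for distractor trials, rotation
# and distractor timing columns.
.realize_conditions <- function(trials, config) {
  app <- config$apparatus
  ecc <- app$target_eccentricity
  has_d <- trials$modality != "none"

  trials$interval_true <- .realized_interval(
    trials$d_onset, trials$d_onset + trials$d_duration,
    trials$on1, trials$off1, trials$on2
  )
  fix_x <- ifelse(trials$fixation_side == "right", ecc, -ecc)
  trials$fix_x <- fix_x
  trials$hemifield_true <- ifelse(
    !has_d | trials$interval_true != "pre_saccadic", "not_applicable",
    ifelse(sign(trials$d_x) == sign(fix_x), "inter", "intra")
  )
  trials$effect_deg <- .effect_lookup(config$effect_map, trials$modality,
                                      trials$interval_true,
                                      trials$hemifield_true)
  # frame units: positive ortho = clockwise side of the saccade direction,
  # i.e. the distractor side for clockwise trials
  eff_frame <- ifelse(!has_d, 0,
                      ifelse(trials$rotation == "clockwise",
                             trials$effect_deg, -trials$effect_deg))
  # bump heights compose additively (superposed orthogonal deviations), so
  # baseline subtraction recovers the evoked component exactly
  h <- function(c_deg) bump_height_for_curvature(c_deg, ecc, trials$dur2[1],
                                                 app$sampling_rate)
  trials$h_total <- h(trials$idio_deg) + h(trials$jit_deg) + h(eff_frame)
  trials
}

# internal: render 1 kHz gaze traces for all trials (vectorized over samples)
.render_traces <- function(trials, config) {
  app <- config$apparatus
  ecc <- app$target_eccentricity
  dt <- 1000 / app$sampling_rate
  t_start <- -config$pre_targets_ms
  t_end <- trials$off2 + config$post_offset_ms
  n_i <- as.integer(floor((t_end - t_start) / dt)) + 1L

  j <- rep(seq_len(nrow(trials)), n_i)
  t <- t_start + (sequence(n_i) - 1) * dt

  u1 <- pmin(pmax((t - trials$on1[j]) / trials$dur1[j], 0), 1)
  s1 <- raised_cosine_progress(u1)
  u2 <- pmin(pmax((t - trials$on2[j]) / trials$dur2[j], 0), 1)
  s2 <- raised_cosine_progress(u2)

  end_y <- ifelse(trials$target2_dir == "up", ecc, -ecc)
  # second-saccade direction and right-hand normal (start = first landing)
  d2x <- 0 - trials$land1_x
  d2y <- end_y - trials$land1_y
  a2 <- sqrt(d2x^2 + d2y^2)
  n2x <- (d2y / a2)
  n2y <- -(d2x / a2)

  bump <- trials$h_total[j] * sin(pi * s2)
  x <- trials$fix_x[j] * (1 - s1) + trials$land1_x[j] * (s1 - s2) +
    s2 * 0 + bump * n2x[j]
  y <- trials$land1_y[j] * (s1 - s2) + s2 * end_y[j] + bump * n2y[j]

  fb <- trials$fixation_break[j] & t >= trials$fb_start[j] &
    t < trials$fb_start[j] + 100
  y[fb] <- y[fb] + 5
  bl <- trials$blink[j] & t >= trials$blink_start[j] &
    t < trials$blink_start[j] + config$blink_duration
  x[bl] <- NA_real_
  y[bl] <- NA_real_

  if (config$noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, config$noise_sd)
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  }
  data.table::data.table(
    trial_id = trials$trial_id[j],
    t_ms = t,
    x_deg = x,
    y_deg = y
  )
}

# internal: assemble the events and ground-truth tables from the trial frame
.events_table <- function(trials) {
  data.table::data.table(
    trial_id = trials$trial_id,
    participant = trials$participant,
    fixation_side = trials$fixation_side,
    target2_dir = trials$target2_dir,
    distractor_modality = trials$modality,
    distractor_x_deg = trials$d_x,
    distractor_y_deg = trials$d_y,
    distractor_onset_ms = trials$d_onset,
    distractor_duration_ms = trials$d_duration
  )
}

.truth_table <- function(trials) {
  data.table::data.table(
    trial_id = trials$trial_id,
    participant = trials$participant,
    on1_true = trials$on1, off1_true = trials$off1,
    on2_true = trials$on2, off2_true = trials$off2,
    effect_curvature_deg = trials$effect_deg,
    baseline_curvature_deg = trials$idio_deg,
    trial_jitter_deg = trials$jit_deg,
    interval_true = trials$interval_true,
    hemifield_true = trials$hemifield_true,
    blink = trials$blink,
    fixation_break = trials$fixation_break,
    landing_error = trials$landing_error
  )
}

#' Simulate one double-step saccade trial
#'
#' Generates the gaze trace and ground-truth record of a single trial from its
#' experimental facts. Latencies, curvature jitter and artifacts are drawn
#' from the current RNG state (call [set.seed()] beforehand for
#' reproducibility); [simulate_experiment()] is the seeded batch interface.
#'
#' @param events One-row data.frame (or list) with `fixation_side`
#'   (`"left"`/`"right"`), `target2_dir` (`"up"`/`"down"`),
#'   `distractor_modality` (`"visual"`, `"auditory"`, `"audiovisual"`,
#'   `"none"`), and, for distractor trials, `distractor_x_deg`,
#'   `distractor_y_deg`, `distractor_onset_ms`, `distractor_duration_ms`.
#' @param participant_params List with optional components
#'   `latency_shift_first`, `latency_shift_second` (ms, added to the modality
#'   latency means) and `idiosyncrasy_deg` (baseline curvature of this
#'   participant for this saccade sequence).
#' @param config A [simulation_config()].
#'
#' @return A list with components `trace` (data.frame `t_ms`, `x_deg`,
#'   `y_deg`), `events` (the completed events row) and `truth` (the
#'   ground-truth record: true saccade on/offsets, injected curvature
#'   components, realized distractor interval, artifact flags).
#' @export
simulate_trial <- function(events, participant_params = list(),
                           config = simulation_config()) {
  events <- as.list(events)
  if (!events$fixation_side %in% c("left", "right") ||
      !events$target2_dir %in% c("up", "down")) {
    stop("events must specify fixation_side left/right and target2_dir up/down",
         call. = FALSE)
  }
  modality <- events$distractor_modality
  if (is.null(modality) || is.na(modality)) modality <- "none"
  pp <- utils::modifyList(
    list(latency_shift_first = 0, latency_shift_second = 0,
         idiosyncrasy_deg = 0),
    participant_params
  )
  trials <- data.frame(
    trial_id = 1L,
    participant = 1L,
    fixation_side = events$fixation_side,
    target2_dir = events$target2_dir,
    modality = modality,
    lat1_shift = pp$latency_shift_first,
    lat2_shift = pp$latency_shift_second,
    idio_deg = pp$idiosyncrasy_deg,
    stringsAsFactors = FALSE
  )
  trials <- .draw_dynamics(trials, config)
  if (modality == "none") {
    trials$rotation <- NA_character_
    trials$d_x <- NA_real_
    trials$d_y <- NA_real_
    trials$d_onset <- NA_real_
    trials$d_duration <- NA_real_
  } else {
    dx <- events$distractor_x_deg
    dy <- events$distractor_y_deg
    if (is.null(dx) || is.na(dx)) {
      stop("distractor trials need distractor_x_deg/distractor_y_deg",
           call. = FALSE)
    }
    tdir <- c(0, if (events$target2_dir == "up") 1 else -1)
    cross <- tdir[1] * dy - tdir[2] * dx
    trials$rotation <- if (cross < 0) "clockwise" else "counterclockwise"
    trials$d_x <- dx
    trials$d_y <- dy
    trials$d_onset <- events$distractor_onset_ms
    trials$d_duration <- events$distractor_duration_ms
  }
  trials <- .realize_conditions(trials, config)
  trace <- .render_traces(trials, config)
  list(
    trace = as.data.frame(trace[, c("t_ms", "x_deg", "y_deg")]),
    events = as.data.frame(.events_table(trials)),
    truth = as.data.frame(.truth_table(trials))
  )
}

#' Simulate a complete double-step saccade experiment
#'
#' Generates a balanced, seeded experiment: for every participant and every
#' saccade sequence (left/right fixation x up/down second target), each
#' distractor modality (visual, auditory, audiovisual) contributes
#' `trials_per_cell` trials aimed at the pre-saccadic window and
#' `trials_per_cell` aimed at the inter-saccadic window, plus
#' `baseline_trials_per_cell` distractor-absent trials. Distractor rotation
#' (clockwise/counterclockwise relative to the second-saccade target) is
#' randomized per trial. Distractor-evoked curvature is injected according to
#' the realized interval (from the true saccade times) and the effect map.
#' Artifacts only flag trials, they never drop rows, so row counts follow the
#' closed-form product.
#'
#' @param config A [simulation_config()]; `config$seed` makes the output
#'   bit-identical across runs.
#'
#' @return An object of class `saccurv_simulation`: a list with `gaze`
#'   (trial_id, t_ms, x_deg, y_deg; missing samples during blinks), `events`
#'   (one row per trial), `truth` (ground truth per trial) and `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(n_participants = 2,
#'                                              trials_per_cell = 2,
#'                                              baseline_trials_per_cell = 4))
#' nrow(sim$events) # 2 * 4 * (3 * 2 * 2 + 4)
simulate_experiment <- function(config = simulation_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  app <- config$apparatus
  n_p <- config$n_participants
  lm <- config$latency_model
  sequences <- expand.grid(
    fixation_side = c("left", "right"), target2_dir = c("up", "down"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )

  # participant-level draws (fixed order)
  lat1_shift <- stats::rnorm(n_p, 0, lm$participant_sd_first)
  lat2_shift <- stats::rnorm(n_p, 0, lm$participant_sd_second)
  idio <- matrix(stats::rnorm(n_p * 4, 0, config$idiosyncrasy_sd),
                 nrow = n_p, ncol = 4)

  cells <- rbind(
    expand.grid(modality = c("visual", "auditory", "audiovisual"),
                timing = c("pre", "inter"),
                rep = seq_len(config$trials_per_cell),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(modality = "none", timing = "none",
                rep = seq_len(config$baseline_trials_per_cell),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  frame <- merge(
    expand.grid(participant = seq_len(n_p), seq_idx = seq_len(4),
                KEEP.OUT.ATTRS = FALSE),
    cells
  )
  frame <- frame[order(frame$participant, frame$seq_idx,
                       match(frame$modality,
                             c("visual", "auditory", "audiovisual", "none")),
                       frame$timing, frame$rep), ]
  trials <- data.frame(
    trial_id = seq_len(nrow(frame)),
    participant = frame$participant,
    fixation_side = sequences$fixation_side[frame$seq_idx],
    target2_dir = sequences$target2_dir[frame$seq_idx],
    modality = frame$modality,
    timing_cell = frame$timing,
    lat1_shift = lat1_shift[frame$participant],
    lat2_shift = lat2_shift[frame$participant],
    idio_deg = idio[cbind(frame$participant, frame$seq_idx)],
    stringsAsFactors = FALSE
  )
  n <- nrow(trials)
  trials <- .draw_dynamics(trials, config)

  # distractor rotation, position and timing (drawn for all trials in fixed
  # order; ignored for distractor-absent trials)
  rot_draw <- stats::runif(n) < 0.5
  has_d <- trials$modality != "none"
  trials$rotation <- ifelse(has_d,
                            ifelse(rot_draw, "clockwise", "counterclockwise"),
                            NA_character_)
  dxy <- .distractor_xy(trials$target2_dir,
                        ifelse(is.na(trials$rotation), "clockwise",
                               trials$rotation),
                        app$distractor_offset)
  trials$d_x <- ifelse(has_d, dxy[, 1], NA_real_)
  trials$d_y <- ifelse(has_d, dxy[, 2], NA_real_)

  # timing: aimed at the intended window, with safety margins so that
  # millisecond-level detection jitter cannot flip the realized condition
  rng <- config$distractor_onset_range
  dur_d <- config$distractor_duration
  u_pre <- stats::runif(n)
  u_inter <- stats::runif(n)
  pre_off <- round(trials$on1 - 140 + u_pre * 130)   # offset in [on1-140, on1-10]
  pre_on <- pmin(pmax(pre_off - dur_d, rng[1]), rng[2])
  lo <- trials$off1 + 25
  hi <- pmax(lo, pmin(rng[2], trials$on2 - dur_d - 125))
  inter_on <- pmin(pmax(round(lo + u_inter * (hi - lo)), rng[1]), rng[2])
  trials$d_onset <- ifelse(!has_d, NA_real_,
                           ifelse(trials$timing_cell == "pre", pre_on,
                                  inter_on))
  trials$d_duration <- ifelse(has_d, dur_d, NA_real_)

  trials <- .realize_conditions(trials, config)
  gaze <- .render_traces(trials, config)

  structure(
    list(
      gaze = gaze,
      events = .events_table(trials),
      truth = .truth_table(trials),
      config = config
    ),
    class = "saccurv_simulation"
  )
}

#' @export
print.saccurv_simulation <- function(x, ...) {
  cat("<saccurv_simulation>\n")
  cat(sprintf("  %d trials, %d participants, %d gaze samples (seed %d)\n",
              nrow(x$events), length(unique(x$events$participant)),
              nrow(x$gaze), x$config$seed))
  invisible(x)
}
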