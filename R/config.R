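#' Apparatus configuration
#'
#' Describes the geometry and recording characteristics of the double-step
#' saccade setup: a screen viewed at a fixed distance, with the fixation and
#' saccade targets on the cardinal axes and four possible distractor positions
#' at the corners of a square centered on the screen midpoint. All positions
#' are expressed in screen-centered degrees of visual angle (positive
#' rightward/upward).
#'
#' @param viewing_distance Viewing distance in cm.
#' @param target_eccentricity Eccentricity of the fixation and saccade targets
#'   from the screen center, in degrees.
#' @param distractor_offset Absolute horizontal and vertical offset of the
#'   distractor positions, in degrees. The four distractor positions are
#'   `(+/- distractor_offset, +/- distractor_offset)`.
#' @param sampling_rate Gaze sampling rate in Hz.
#' @param fixation_radius Radius, in degrees, of the virtual circle used for
#'   online fixation and landing control.
#'
#' @return An object of class `apparatus_config`.
#' @export
#' @examples
#' app <- apparatus_config()
#' distractor_positions(app)
apparatus_config <- function(viewing_distance = 76.5,
                             target_eccentricity = 15,
                             distractor_offset = 7.5,
                             sampling_rate = 1000,
                             fixation_radius = 3.5) {
  stopifnot(
    viewing_distance > 0,
    target_eccentricity > 0,
    distractor_offset > 0,
    fixation_radius > 0
  )
  if (sampling_rate < 250) {
    stop("sampling_rate must be at least 250 Hz", call. = FALSE)
  }
  structure(
    list(
      viewing_distance = viewing_distance,
      target_eccentricity = target_eccentricity,
      distractor_offset = distractor_offset,
      sampling_rate = sampling_rate,
      fixation_radius = fixation_radius
    ),
    class = "apparatus_config"
  )
}

#' Distractor positions of an apparatus
#'
#' @param apparatus An [apparatus_config()].
#' @return A data.frame with columns `x_deg`, `y_deg`: the four corners of the
#'   distractor square.
#' @export
distractor_positions <- function(apparatus = apparatus_config()) {
  d <- apparatus$distractor_offset
  data.frame(
    x_deg = c(d, -d, -d, d),
    y_deg = c(d, d, -d, -d)
  )
}

#' Saccade detection parameters
#'
#' Parameters of the velocity-distribution saccade detector: gaze speed is
#' smoothed with a moving average over `window` consecutive samples and an
#' event is a run of at least `min_duration` ms during which the smoothed
#' speed exceeds `median + k * SD` of the trial's smoothed speed.
#'
#' @param window Length of the moving-average window, in samples.
#' @param k Threshold multiplier in SD units.
#' @param min_duration Minimum above-threshold duration, in ms.
#' @param merge_gap Runs separated by less than this many ms are merged, to
#'   avoid double-counting events split by dynamic overshoot.
#' @param sd_method How the SD in the threshold is estimated. `"robust"`
#'   (default) uses the median-based estimator
#'   `sqrt(median(v^2) - median(v)^2)`, which is insensitive to the saccade
#'   samples themselves and keeps the threshold anchored to the fixation noise
#'   level; `"classic"` uses [stats::sd()] over the whole trial.
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(window = 20, k = 3, min_duration = 20,
                             merge_gap = 10,
                             sd_method = c("robust", "classic")) {
  sd_method <- match.arg(sd_method)
  stopifnot(window >= 2, k > 0, min_duration > 0, merge_gap >= 0)
  structure(
    list(
      window = as.integer(window), k = k,
      min_duration = min_duration, merge_gap = merge_gap,
      sd_method = sd_method
    ),
    class = "detection_params"
  )
}

#' Trial selection criteria
#'
#' Inclusion rules applied offline to each trial: fixation must be held within
#' `fixation_radius` of the fixation target before the saccade targets appear,
#' each saccade must start and land within the stated radii of its source and
#' goal targets, latencies must stay under the caps, and no blink may occur.
#' `pre_window` and `inter_gap` define the distractor-interval windows: a
#' pre-saccadic distractor ends in the last `pre_window` ms before the first
#' saccade onset; an inter-saccadic distractor starts after the first saccade
#' offset and ends at least `inter_gap` ms before the second saccade onset.
#'
#' @param fixation_radius Radius (deg) for the fixation-hold and saccade-start
#'   checks.
#' @param landing_radius Radius (deg) for the saccade-landing checks.
#' @param max_latency_first Latency cap (ms) for the first saccade.
#' @param max_latency_second Latency cap (ms) for the second saccade.
#' @param pre_window Pre-saccadic distractor window (ms).
#' @param inter_gap Minimum gap (ms) between distractor offset and second
#'   saccade onset for inter-saccadic trials.
#' @param hold_duration Duration (ms) of the fixation-hold check before the
#'   saccade targets onset.
#'
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(fixation_radius = 3.5,
                               landing_radius = 3.5,
                               max_latency_first = 400,
                               max_latency_second = 700,
                               pre_window = 150,
                               inter_gap = 100,
                               hold_duration = 200) {
  vals <- c(fixation_radius, landing_radius, max_latency_first,
            max_latency_second, pre_window, inter_gap, hold_duration)
  if (any(vals <= 0)) stop("all selection criteria must be strictly positive",
                           call. = FALSE)
  structure(
    list(
      fixation_radius = fixation_radius, landing_radius = landing_radius,
      max_latency_first = max_latency_first,
      max_latency_second = max_latency_second,
      pre_window = pre_window, inter_gap = inter_gap,
      hold_duration = hold_duration
    ),
    class = "selection_criteria"
  )
}

#' Default distractor effect map
#'
#' Expected distractor-evoked curvature angle (deg) per condition, used by the
#' synthetic-data generator. Negative values mean curvature away from the
#' distractor's screen position. Defaults are the condition means observed in
#' the reference experiment with eight participants: inter-saccadic distractors
#' evoke the strongest repulsion, pre-saccadic distractors weaker repulsion
#' that differs between inter- and intra-hemifield configurations.
#'
#' @return A data.frame with columns `modality`, `interval`, `hemifield`,
#'   `curvature_deg`. `hemifield` is `"any"` for inter-saccadic rows.
#' @export
default_effect_map <- function() {
  data.frame(
    modality = rep(c("visual", "auditory", "audiovisual"), times = 3),
    interval = rep(c("inter_saccadic", "pre_saccadic", "pre_saccadic"),
                   each = 3),
    hemifield = rep(c("any", "inter", "intra"), each = 3),
    curvature_deg = c(-2.65, -0.52, -3.34,
                      -0.76, -0.58, -1.05,
                      -1.38, 0.24, -1.15),
    stringsAsFactors = FALSE
  )
}

#' Default saccade latency model
#'
#' Latency means (ms, relative to saccade-targets onset) per distractor
#' modality for the first and second saccade, with between-participant and
#' within-participant (trial) SDs. Means are the group means of the reference
#' experiment; between-participant SDs are the printed SEMs scaled by
#' `sqrt(8)`; trial SDs are generator assumptions. Latencies are sampled from
#' Gaussians truncated at the online caps (400/700 ms) minus a safety margin,
#' mirroring the online abort rule.
#'
#' @return A list with components `first`, `second` (named numeric vectors of
#'   means per modality), `participant_sd_first`, `participant_sd_second`,
#'   `trial_sd_first`, `trial_sd_second`.
#' @export
default_latency_model <- function() {
  list(
    first = c(visual = 172.02, auditory = 160.50, audiovisual = 163.88,
              none = 179.44),
    second = c(visual = 497.28, auditory = 462.92, audiovisual = 473.86,
               none = 480.99),
    participant_sd_first = 6.18 * sqrt(8),
    participant_sd_second = 16.21 * sqrt(8),
    trial_sd_first = 30,
    trial_sd_second = 50
  )
}

#' Synthetic experiment configuration
#'
#' Parameters of the synthetic double-step saccade experiment generator. A
#' generated experiment is balanced over condition cells defined by distractor
#' modality (visual, auditory, audiovisual) x intended timing (pre- vs
#' inter-saccadic) x saccade sequence (left/right fixation x up/down second
#' target), plus distractor-absent cells per sequence.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_cell Trials per (modality x timing x sequence) cell.
#' @param baseline_trials_per_cell Distractor-absent trials per sequence.
#' @param distractor_onset_range Allowed distractor onset interval (ms,
#'   relative to saccade-targets onset).
#' @param distractor_duration Distractor duration (ms).
#' @param latency_model See [default_latency_model()].
#' @param duration_slope,duration_intercept Main-sequence saccade duration
#'   model: `duration_ms = duration_slope * amplitude_deg + duration_intercept`.
#' @param effect_map See [default_effect_map()].
#' @param idiosyncrasy_sd SD (deg) of the per-participant, per-sequence
#'   baseline curvature of the second saccade.
#' @param trial_curvature_sd SD (deg) of the trial-to-trial curvature jitter.
#' @param noise_sd SD (deg) of isotropic Gaussian gaze position noise, added
#'   after path construction.
#' @param artifact_rates Named list of probabilities: `blink`,
#'   `fixation_break`, `landing_error`.
#' @param blink_duration Duration (ms) of an injected blink (run of missing
#'   samples).
#' @param pre_targets_ms Trace duration recorded before the saccade-targets
#'   onset (ms).
#' @param post_offset_ms Trace duration recorded after the second saccade
#'   offset (ms).
#' @param seed Integer seed; a fixed seed makes the generated tables
#'   bit-identical across runs.
#' @param apparatus An [apparatus_config()].
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 8,
                              trials_per_cell = 48,
                              baseline_trials_per_cell = 96,
                              distractor_onset_range = c(-100, 300),
                              distractor_duration = 50,
                              latency_model = default_latency_model(),
                              duration_slope = 2.2,
                              duration_intercept = 21,
                              effect_map = default_effect_map(),
                              idiosyncrasy_sd = 1,
                              trial_curvature_sd = 1.5,
                              noise_sd = 0.05,
                              artifact_rates = list(blink = 0.03,
                                                    fixation_break = 0.03,
                                                    landing_error = 0.03),
                              blink_duration = 80,
                              pre_targets_ms = 250,
                              post_offset_ms = 80,
                              seed = 1L,
                              apparatus = apparatus_config()) {
  if (n_participants <= 0 || trials_per_cell <= 0 ||
      baseline_trials_per_cell <= 0) {
    stop("participant and trial counts must be strictly positive",
         call. = FALSE)
  }
  stopifnot(
    length(distractor_onset_range) == 2,
    distractor_onset_range[1] < distractor_onset_range[2],
    distractor_duration > 0,
    idiosyncrasy_sd >= 0, trial_curvature_sd >= 0, noise_sd >= 0,
    inherits(apparatus, "apparatus_config")
  )
  rates <- unlist(artifact_rates[c("blink", "fixation_break", "landing_error")])
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("artifact_rates must contain probabilities for blink, fixation_break, landing_error",
         call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_cell = as.integer(trials_per_cell),
      baseline_trials_per_cell = as.integer(baseline_trials_per_cell),
      distractor_onset_range = distractor_onset_range,
      distractor_duration = distractor_duration,
      latency_model = latency_model,
      duration_slope = duration_slope,
      duration_intercept = duration_intercept,
      effect_map = effect_map,
      idiosyncrasy_sd = idiosyncrasy_sd,
      trial_curvature_sd = trial_curvature_sd,
      noise_sd = noise_sd,
      artifact_rates = as.list(rates),
      blink_duration = blink_duration,
      pre_targets_ms = pre_targets_ms,
      post_offset_ms = post_offset_ms,
      seed = as.integer(seed),
      apparatus = apparatus
    ),
    class = "simulation_config"
  )
}

#' @export
print.apparatus_config <- function(x, ...) {
  cat("<apparatus_config>\n")
  cat(sprintf("  viewing distance: %.1f cm, sampling: %g Hz\n",
              x$viewing_distance, x$sampling_rate))
  cat(sprintf("  targets at %g deg, distractors at (+/-%g, +/-%g) deg, fixation radius %g deg\n",
              x$target_eccentricity, x$distractor_offset, x$distractor_offset,
              x$fixation_radius))
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  n_cells <- 3 * 2 * 4
  n_trials <- x$n_participants *
    (n_cells * x$trials_per_cell + 4 * x$baseline_trials_per_cell)
  cat("<simulation_config>\n")
  cat(sprintf("  %d participants, %d trials/cell (+%d baseline/sequence): %d trials total\n",
              x$n_participants, x$trials_per_cell, x$baseline_trials_per_cell,
              n_trials))
  cat(sprintf("  distractor onsets in [%g, %g] ms, duration %g ms, seed %d\n",
              x$distractor_onset_range[1], x$distractor_onset_range[2],
              x$distractor_duration, x$seed))
  invisible(x)
}

# internal: Euclidean distance between two xy points
.dist2 <- function(x0, y0, x1, y1) sqrt((x1 - x0)^2 + (y1 - y0)^2)

# internal: data.frame constructor without the validation overhead of
# data.frame() (hot loops build millions of small frames)
.fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}
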