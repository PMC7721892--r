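# Trial selection and classification: inclusion filters, distractor-interval
# windows (pre- vs inter-saccadic), hemifield taxonomy and the
# clockwise/counterclockwise distractor rotation.

.rejection_reasons <- c(
  "blink", "fixation_break", "late_first_saccade", "late_second_saccade",
  "first_start_error", "first_landing_error", "second_start_error",
  "second_landing_error", "too_few_saccades", "missing_center_saccade",
  "missing_second_saccade"
)

#' Validate a double-step trial against the inclusion criteria
#'
#' A trial is valid iff fixation was held within `fixation_radius` of the
#' fixation target over the `hold_duration` ms preceding the saccade-targets
#' onset, the first saccade started at the fixation target and landed within
#' `landing_radius` of the screen center, the second saccade started at the
#' screen center and landed within `landing_radius` of the second target,
#' both latencies are under their caps, and no blink (missing samples)
#' occurred during the trial. Failures are reported as a single primary
#' reason, checked in the order: blink, fixation break, late first/second
#' saccade, first start/landing, second start/landing.
#'
#' @param events One-row data.frame with `fixation_side`, `target2_dir`.
#' @param first,second One-row `saccade_table` rows from [assign_sequence()].
#' @param criteria A [selection_criteria()].
#' @param apparatus An [apparatus_config()].
#' @param trace Optional gaze trace, used for the blink and fixation-hold
#'   checks; alternatively supply `has_blink` / `fixation_held` directly.
#' @param has_blink,fixation_held Optional precomputed logicals overriding the
#'   trace-derived checks.
#'
#' @return A list with `valid` (logical) and `reason` (`NA` or one of the
#'   rejection reasons).
#' @export
validate_trial <- function(events, first, second,
                           criteria = selection_criteria(),
                           apparatus = apparatus_config(),
                           trace = NULL, has_blink = NULL,
                           fixation_held = NULL) {
  ecc <- apparatus$target_eccentricity
  fix_x <- if (identical(events$fixation_side, "right")) ecc else -ecc
  t2_y <- if (identical(events$target2_dir, "down")) -ecc else ecc

  if (is.null(has_blink) && !is.null(trace)) {
    has_blink <- anyNA(trace$x_deg) || anyNA(trace$y_deg)
  }
  if (is.null(fixation_held) && !is.null(trace)) {
    pre <- trace$t_ms >= -criteria$hold_duration & trace$t_ms < 0
    dev <- .dist2(trace$x_deg[pre], trace$y_deg[pre], fix_x, 0)
    fixation_held <- all(dev <= criteria$fixation_radius, na.rm = TRUE)
  }
  fail <- function(reason) list(valid = FALSE, reason = reason)

  if (isTRUE(has_blink)) return(fail("blink"))
  if (isFALSE(fixation_held)) return(fail("fixation_break"))
  if (first$latency > criteria$max_latency_first) {
    return(fail("late_first_saccade"))
  }
  if (second$latency > criteria$max_latency_second) {
    return(fail("late_second_saccade"))
  }
  if (.dist2(first$x0, first$y0, fix_x, 0) > criteria$fixation_radius) {
    return(fail("first_start_error"))
  }
  if (.dist2(first$x1, first$y1, 0, 0) > criteria$landing_radius) {
    return(fail("first_landing_error"))
  }
  if (.dist2(second$x0, second$y0, 0, 0) > criteria$fixation_radius) {
    return(fail("second_start_error"))
  }
  if (.dist2(second$x1, second$y1, 0, t2_y) > criteria$landing_radius) {
    return(fail("second_landing_error"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Classify the distractor interval of a trial
#'
#' Labels a distractor-present trial `pre_saccadic` if the distractor ended in
#' the last `pre_window` ms preceding the first saccade onset (offset in
#' `[onset1 - pre_window, onset1)`), `inter_saccadic` if it started after the
#' first saccade offset and ended at least `inter_gap` ms before the second
#' saccade onset, and `excluded` otherwise (in particular, late distractors
#' still on within the last `inter_gap` ms before the second saccade).
#' Distractor-absent trials are labelled `no_distractor`.
#'
#' @inheritParams validate_trial
#' @return One of `"pre_saccadic"`, `"inter_saccadic"`, `"excluded"`,
#'   `"no_distractor"`.
#' @export
classify_distractor_interval <- function(events, first, second,
                                         criteria = selection_criteria()) {
  modality <- events$distractor_modality
  if (is.null(modality) || is.na(modality) || modality == "none") {
    return("no_distractor")
  }
  d_on <- events$distractor_onset_ms
  d_off <- d_on + events$distractor_duration_ms
  if (is.na(d_on) || events$distractor_duration_ms < 0) {
    stop("malformed events: distractor offset precedes its onset",
         call. = FALSE)
  }
  if (d_off >= first$onset_t - criteria$pre_window && d_off < first$onset_t) {
    "pre_saccadic"
  } else if (d_on > first$offset_t &&
             d_off <= second$onset_t - criteria$inter_gap) {
    "inter_saccadic"
  } else {
    "excluded"
  }
}

#' Classify the hemifield relation of a pre-saccadic distractor
#'
#' For a pre-saccadic trial, the first (horizontal) saccade either carries the
#' distractor's eye-centered representation into the opposite visual hemifield
#' or keeps it in the same one. The trial is `inter`-hemifield when the
#' distractor's horizontal position lies strictly between the initial fixation
#' position and the screen center (same side as fixation), and
#' `intra`-hemifield when it lies on the opposite side.
#'
#' @inheritParams validate_trial
#' @return `"inter"` or `"intra"`.
#' @export
classify_hemifield <- function(events, apparatus = apparatus_config()) {
  ecc <- apparatus$target_eccentricity
  fix_x <- if (identical(events$fixation_side, "right")) ecc else -ecc
  dx <- events$distractor_x_deg
  if (is.na(dx) || dx == 0) {
    stop("distractor on the vertical midline: hemifield undefined",
         call. = FALSE)
  }
  if (sign(dx) == sign(fix_x)) {
    if (abs(dx) >= abs(fix_x)) {
      stop("distractor beyond the fixation target: not a legal position",
           call. = FALSE)
    }
    "inter"
  } else {
    "intra"
  }
}

#' Eye-to-distractor eccentricity
#'
#' Distance between the fixation position and the distractor position. The
#' default (`"planar"`) is the Euclidean distance in screen-centered degree
#' coordinates, matching the screen-coordinate bookkeeping of the analysis;
#' it is an approximation to the true angular separation, which is available
#' as `method = "angular"` (angle between the two lines of sight on a flat
#' screen at `viewing_distance`).
#'
#' @param fixation,distractor Numeric length-2 (x, y) positions in degrees.
#' @param method `"planar"` or `"angular"`.
#' @param viewing_distance Viewing distance in cm (angular method only).
#' @return Eccentricity in degrees.
#' @export
#' @examples
#' eye_distractor_eccentricity(c(15, 0), c(7.5, 7.5))   # 10.61
#' eye_distractor_eccentricity(c(15, 0), c(-7.5, 7.5))  # 23.72
eye_distractor_eccentricity <- function(fixation, distractor,
                                        method = c("planar", "angular"),
                                        viewing_distance = 76.5) {
  method <- match.arg(method)
  if (method == "planar") {
    return(.dist2(fixation[1], fixation[2], distractor[1], distractor[2]))
  }
  to_vec <- function(p) c(tan(p[1] * pi / 180), tan(p[2] * pi / 180), 1)
  a <- to_vec(fixation)
  b <- to_vec(distractor)
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Distractor rotation relative to the second-saccade target
#'
#' Whether the distractor was presented clockwise or counterclockwise relative
#' to the second-saccade target position, from the signed angle (about the
#' screen center) between the target direction and the distractor direction.
#'
#' @inheritParams validate_trial
#' @return `"clockwise"` or `"counterclockwise"`.
#' @export
distractor_rotation <- function(events) {
  dx <- events$distractor_x_deg
  dy <- events$distractor_y_deg
  if (is.na(dx) || is.na(dy)) stop("no distractor present", call. = FALSE)
  ty <- if (identical(events$target2_dir, "down")) -1 else 1
  cross <- 0 * dy - ty * dx
  if (abs(cross) < 1e-9) {
    stop("distractor collinear with the second-saccade target", call. = FALSE)
  }
  if (cross < 0) "clockwise" else "counterclockwise"
}

#' Classify one trial (validity, interval, hemifield, rotation)
#'
#' Convenience wrapper combining [validate_trial()],
#' [classify_distractor_interval()], [classify_hemifield()] and
#' [distractor_rotation()] into a single classification record.
#'
#' @inheritParams validate_trial
#' @param assignment Result of [assign_sequence()] for this trial.
#' @return A list: `valid`, `reason`, `interval`, `hemifield`, `rotation`.
#' @export
classify_trial <- function(events, assignment,
                           criteria = selection_criteria(),
                           apparatus = apparatus_config(),
                           trace = NULL, has_blink = NULL,
                           fixation_held = NULL) {
  res <- list(
    valid = FALSE, reason = NA_character_, interval = NA_character_,
    hemifield = "not_applicable", rotation = "none"
  )
  if (!assignment$valid) {
    res$reason <- assignment$reason
    return(res)
  }
  v <- validate_trial(events, assignment$first, assignment$second, criteria,
                      apparatus, trace, has_blink, fixation_held)
  res$valid <- v$valid
  res$reason <- v$reason
  if (!v$valid) return(res)
  res$interval <- classify_distractor_interval(events, assignment$first,
                                               assignment$second, criteria)
  if (res$interval %in% c("pre_saccadic", "inter_saccadic")) {
    res$rotation <- distractor_rotation(events)
  }
  if (res$interval == "pre_saccadic") {
    res$hemifield <- classify_hemifield(events, apparatus)
  }
  res
}
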