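# Velocity-threshold saccade detection.
#
# Gaze speed is obtained from centered finite differences of position, scaled
# to deg/s, then smoothed with a trailing moving average over `window`
# consecutive samples. A saccade is a run of at least `min_duration` ms during
# which the smoothed speed exceeds median + k * SD of the trial's smoothed
# speed distribution; by default the SD is the median-based (robust) estimate
# so the threshold is anchored to the fixation noise level rather than being
# inflated by the saccade samples themselves.

#' Compute a smoothed gaze speed trace
#'
#' @param trace Gaze trace: data.frame with `t_ms`, `x_deg`, `y_deg`, sampled
#'   at a uniform rate. Missing samples (blinks) propagate as undefined speed.
#' @param params A [detection_params()].
#'
#' @return A data.frame of class `velocity_trace` with columns `t_ms` and `v`
#'   (smoothed speed, deg/s; `NA` over the smoothing margin and around
#'   missing samples), plus a `"dt_ms"` attribute.
#' @export
compute_velocity <- function(trace, params = detection_params()) {
  n <- nrow(trace)
  if (n < params$window + 1) {
    stop("trace too short for the smoothing window", call. = FALSE)
  }
  dts <- diff(trace$t_ms)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6)) {
    stop("trace timestamps are not uniformly sampled", call. = FALSE)
  }
  rate <- 1000 / dt
  x <- trace$x_deg
  y <- trace$y_deg
  lead <- c(2:n, n)
  lag <- c(1, 1:(n - 1))
  vx <- (x[lead] - x[lag]) / 2 * rate
  vy <- (y[lead] - y[lag]) / 2 * rate
  vx[c(1, n)] <- NA_real_
  vy[c(1, n)] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  v <- data.table::frollmean(speed, params$window, align = "right")
  out <- .fast_df(list(t_ms = trace$t_ms, v = v, v_raw = speed))
  attr(out, "dt_ms") <- dt
  class(out) <- c("velocity_trace", "data.frame")
  out
}

# internal: robust SD of a speed distribution: the scaled median absolute
# deviation. (The classic median-based variance estimator
# median(v^2) - median(v)^2 is identically zero for a positive-valued
# series, since squaring is monotone there.)
.robust_sd <- function(v) {
  stats::mad(v)
}

#' Detect saccades in a velocity trace
#'
#' Finds maximal runs of samples whose smoothed speed strictly exceeds
#' `median(v) + k * SD(v)` (computed per trial over the defined samples) and
#' lasts at least `min_duration` ms. Runs separated by less than
#' `params$merge_gap` ms are merged first (dynamic overshoot protection).
#' The saccade onset is the first sample of the run, refined backward (by at
#' most one smoothing window) to the last sample whose speed still sat at the
#' trial's median level — this compensates the crossing delay introduced by
#' the trailing smoothing window; the offset is the first sample after the
#' run at which the speed has fallen back below threshold.
#'
#' @param vel A `velocity_trace` from [compute_velocity()].
#' @param params A [detection_params()].
#' @param trace Optional gaze trace (same trial); when supplied, start/end
#'   positions and the amplitude of each saccade are filled in.
#'
#' @return A data.frame of class `saccade_table`, one row per saccade:
#'   `onset_t`, `offset_t`, `duration`, `x0`, `y0`, `x1`, `y1`, `amplitude`,
#'   `peak_v`, `latency` (onset time on the trial clock, i.e. relative to
#'   saccade-targets onset at `t = 0`). Empty when nothing crosses threshold.
#' @export
detect_saccades <- function(vel, params = detection_params(), trace = NULL) {
  v <- vel$v
  ok <- !is.na(v)
  if (!any(ok)) stop("velocity trace is entirely undefined", call. = FALSE)
  dt <- attr(vel, "dt_ms")
  if (is.null(dt)) dt <- diff(vel$t_ms)[1]
  vv <- v[ok]
  sdv <- if (params$sd_method == "robust") .robust_sd(vv) else stats::sd(vv)
  threshold <- stats::median(vv) + params$k * sdv

  above <- ok & v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  empty <- .fast_df(list(
    onset_t = numeric(0), offset_t = numeric(0), duration = numeric(0),
    x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
    amplitude = numeric(0), peak_v = numeric(0), latency = numeric(0)
  ))
  class(empty) <- c("saccade_table", "data.frame")
  if (nrow(runs) == 0) return(empty)

  # merge runs separated by a short sub-threshold gap
  if (nrow(runs) > 1) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2:nrow(runs)) {
      gap <- (runs[i, "start"] - runs[i - 1, "end"] - 1L) * dt
      gap_idx <- seq.int(runs[i - 1, "end"] + 1L, runs[i, "start"] - 1L)
      if (gap < params$merge_gap && all(ok[gap_idx])) {
        runs[i, "start"] <- runs[i - 1, "start"]
        keep[i - 1] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]
  }

  dur <- (runs[, "end"] - runs[, "start"] + 1L) * dt
  runs <- runs[dur >= params$min_duration, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  # refine each onset backward from the threshold crossing to the last sample
  # whose raw (unsmoothed) speed still sat at the baseline (median) level:
  # the trailing smoothing window delays the crossing by several ms, while
  # the movement itself starts where the raw speed leaves the baseline. The
  # raw series is used because its noise is uncorrelated sample-to-sample.
  vr <- vel$v_raw
  if (is.null(vr)) vr <- v
  anchor <- stats::quantile(vr, 0.25, na.rm = TRUE, names = FALSE)
  onset_i <- runs[, "start"]
  for (r in seq_along(onset_i)) {
    j <- onset_i[r]
    lim <- max(j - params$window, 1L)
    while (j > lim && !is.na(vr[j - 1]) && vr[j - 1] > anchor) j <- j - 1L
    onset_i[r] <- j
  }
  offset_i <- pmin(runs[, "end"] + 1L, length(v))
  nr <- nrow(runs)
  na <- rep(NA_real_, nr)
  out <- .fast_df(list(
    onset_t = vel$t_ms[onset_i],
    offset_t = vel$t_ms[offset_i],
    duration = (offset_i - onset_i) * dt,
    x0 = na, y0 = na, x1 = na, y1 = na,
    amplitude = na,
    peak_v = vapply(seq_len(nr), function(i) {
      max(v[runs[i, "start"]:runs[i, "end"]], na.rm = TRUE)
    }, numeric(1)),
    latency = vel$t_ms[onset_i]
  ))
  if (!is.null(trace)) {
    i0 <- match(out$onset_t, trace$t_ms)
    i1 <- match(out$offset_t, trace$t_ms)
    out$x0 <- trace$x_deg[i0]
    out$y0 <- trace$y_deg[i0]
    out$x1 <- trace$x_deg[i1]
    out$y1 <- trace$y_deg[i1]
    out$amplitude <- .dist2(out$x0, out$y0, out$x1, out$y1)
  }
  class(out) <- c("saccade_table", "data.frame")
  out
}

#' Assign detected saccades to the double-step sequence
#'
#' Identifies the first (fixation -> screen center) and second (center ->
#' vertical target) task saccades among the detected movements. The first
#' saccade is the earliest one starting within the fixation radius of the
#' fixation target and approaching the screen center substantially; the
#' second is the earliest later movement of at least 5 degrees amplitude
#' that starts near the screen center (or near the first saccade's landing
#' point) and moves away from the center. Small corrective movements are
#' thereby ignored. Trials without a geometrically consistent pair are
#' flagged, not silently fixed.
#'
#' @param saccades A `saccade_table` with positions filled in.
#' @param events One-row data.frame with `fixation_side`.
#' @param apparatus An [apparatus_config()].
#'
#' @return A list with `first` and `second` (one-row data.frames or `NULL`),
#'   `valid` (logical) and `reason` (`NA` or one of `"too_few_saccades"`,
#'   `"missing_center_saccade"`, `"missing_second_saccade"`).
#' @export
assign_sequence <- function(saccades, events,
                            apparatus = apparatus_config()) {
  invalid <- function(reason) {
    list(first = NULL, second = NULL, valid = FALSE, reason = reason)
  }
  if (nrow(saccades) < 2) return(invalid("too_few_saccades"))
  ecc <- apparatus$target_eccentricity
  fr <- apparatus$fixation_radius
  fix_x <- if (identical(events$fixation_side, "right")) ecc else -ecc

  d_start_fix <- .dist2(saccades$x0, saccades$y0, fix_x, 0)
  d_start_ctr <- .dist2(saccades$x0, saccades$y0, 0, 0)
  d_end_ctr <- .dist2(saccades$x1, saccades$y1, 0, 0)
  approach <- d_end_ctr < d_start_ctr - 5

  first_ok <- which(!is.na(d_start_fix) & d_start_fix <= fr & approach)
  if (length(first_ok) == 0) return(invalid("missing_center_saccade"))
  i1 <- first_ok[1]
  first <- saccades[i1, , drop = FALSE]

  later <- which(saccades$onset_t >= first$offset_t)
  later <- setdiff(later, seq_len(i1))
  d_start_land <- .dist2(saccades$x0, saccades$y0, first$x1, first$y1)
  second_ok <- later[
    !is.na(saccades$amplitude[later]) & saccades$amplitude[later] >= 5 &
      (d_start_ctr[later] <= fr | d_start_land[later] <= fr) &
      d_end_ctr[later] > d_start_ctr[later] + 5
  ]
  if (length(second_ok) == 0) return(invalid("missing_second_saccade"))
  second <- saccades[second_ok[1], , drop = FALSE]
  rownames(first) <- rownames(second) <- NULL
  list(first = first, second = second, valid = TRUE, reason = NA_character_)
}
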