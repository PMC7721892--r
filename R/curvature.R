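#' Rotate a second saccade into the saccade-direction frame
#'
#' Expresses the gaze samples of a detected second saccade in a coordinate
#' frame anchored at the saccade start: `along` is the (signed) progress
#' toward the saccade goal and `ortho` the orthogonal deviation. The rotation
#' is rigid: the along axis is the unit vector from the saccade start to the
#' second-saccade target, and the ortho axis is its right-hand normal, so that
#' positive `ortho` values lie on the clockwise side of the movement
#' direction. Because distractors are placed 45 degrees clockwise or
#' counterclockwise from the second-saccade target, a clockwise distractor
#' always lies on the positive-ortho side; [apply_sign_convention()] later
#' flips counterclockwise trials so that, across all trials, positive means
#' toward the distractor.
#'
#' @param second One-row data.frame (or list) describing the second saccade,
#'   with fields `onset_t`, `offset_t`, `x0`, `y0`.
#' @param trace Gaze trace of the trial: data.frame with `t_ms`, `x_deg`,
#'   `y_deg`.
#' @param events One-row data.frame with the trial's `target2_dir`
#'   (`"up"`/`"down"`).
#' @param apparatus An [apparatus_config()]; sets the target eccentricity.
#'
#' @return A data.frame of class `rotated_trajectory` with columns `t_ms`,
#'   `along`, `ortho` (degrees), and an `"amplitude"` attribute (the along
#'   extent of the saccade).
#' @export
rotate_to_upward <- function(second, trace, events,
                             apparatus = apparatus_config()) {
  sel <- trace$t_ms >= second$onset_t & trace$t_ms <= second$offset_t
  samples <- trace[sel, , drop = FALSE]
  if (nrow(samples) < 5) {
    stop("second saccade has fewer than 5 gaze samples", call. = FALSE)
  }
  tdir <- if (identical(events$target2_dir, "down")) -1 else 1
  target <- c(0, tdir * apparatus$target_eccentricity)
  start <- c(second$x0, second$y0)
  u <- target - start
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate saccade: start coincides with target",
                      call. = FALSE)
  u <- u / nu
  n_right <- c(u[2], -u[1])
  dx <- samples$x_deg - start[1]
  dy <- samples$y_deg - start[2]
  out <- .fast_df(list(
    t_ms = samples$t_ms,
    along = dx * u[1] + dy * u[2],
    ortho = dx * n_right[1] + dy * n_right[2]
  ))
  attr(out, "amplitude") <- out$along[nrow(out)]
  class(out) <- c("rotated_trajectory", "data.frame")
  out
}

#' Resample a rotated trajectory onto a monotonic along-axis grid
#'
#' Averages the orthogonal deviation within equal-width bins of the along-axis
#' coordinate, spanning `[0, amplitude]`. This turns the raw, possibly
#' non-monotonic sample sequence (e.g. with dynamic overshoot) into a profile
#' indexed by a strictly increasing grid. Empty bins are filled by linear
#' interpolation between neighbouring occupied bins (constant extension at the
#' edges).
#'
#' @param rot A `rotated_trajectory` (or any data.frame with `along`, `ortho`).
#' @param n_bins Number of bins.
#' @param amplitude Along-axis extent; defaults to the trajectory's
#'   `"amplitude"` attribute, falling back to the last along value.
#'
#' @return A data.frame of class `monotonic_profile` with columns `grid` (bin
#'   centers, strictly increasing) and `ortho` (mean orthogonal deviation),
#'   plus attributes `amplitude` and `n_samples`.
#' @export
monotonic_resample <- function(rot, n_bins = 50, amplitude = NULL) {
  if (is.null(amplitude)) {
    amplitude <- attr(rot, "amplitude")
    if (is.null(amplitude)) amplitude <- rot$along[nrow(rot)]
  }
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("saccade amplitude must be strictly positive", call. = FALSE)
  }
  if (nrow(rot) < n_bins / 4) {
    stop("too few samples for the requested number of bins", call. = FALSE)
  }
  width <- amplitude / n_bins
  # the 1e-9 tolerance keeps samples sitting exactly on a bin edge in a
  # stable bin under rigid motions of the scene
  idx <- pmin(pmax(ceiling(rot$along / width - 1e-9), 1L), n_bins)
  sums <- tabulate_sum(idx, rot$ortho, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  grid <- (seq_len(n_bins) - 0.5) * width
  ortho <- rep(NA_real_, n_bins)
  occ <- counts > 0
  ortho[occ] <- sums[occ] / counts[occ]
  if (!all(occ)) {
    ortho <- stats::approx(grid[occ], ortho[occ], xout = grid, rule = 2)$y
  }
  out <- .fast_df(list(grid = grid, ortho = ortho))
  attr(out, "amplitude") <- amplitude
  attr(out, "n_samples") <- nrow(rot)
  class(out) <- c("monotonic_profile", "data.frame")
  out
}

# internal: per-bin sums (base tabulate only counts)
tabulate_sum <- function(idx, values, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(values, group = idx, reorder = TRUE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Subtract a distractor-absent baseline profile
#'
#' Removes the participant's idiosyncratic trajectory shape by subtracting the
#' mean profile of distractor-absent trials of the same participant and
#' saccade sequence. If the baseline grid differs from the trial grid, the
#' baseline is re-gridded by linear interpolation.
#'
#' @param profile A `monotonic_profile` for one trial.
#' @param baseline A baseline profile (`grid`, `ortho`), ideally carrying an
#'   `"n_trials"` attribute; baselines built from fewer than 5 trials are
#'   flagged via the `"baseline_warning"` attribute of the result.
#'
#' @return A data.frame of class `normalized_trajectory` with columns `grid`
#'   and `ortho` (baseline-subtracted orthogonal deviation).
#' @export
normalize_trajectory <- function(profile, baseline) {
  b_ortho <- baseline$ortho
  if (length(b_ortho) != nrow(profile) ||
      max(abs(baseline$grid - profile$grid)) > 1e-9) {
    b_ortho <- stats::approx(baseline$grid, baseline$ortho,
                             xout = profile$grid, rule = 2)$y
  }
  out <- data.frame(grid = profile$grid, ortho = profile$ortho - b_ortho)
  n_base <- attr(baseline, "n_trials")
  attr(out, "baseline_warning") <- !is.null(n_base) && n_base < 5
  attr(out, "amplitude") <- attr(profile, "amplitude")
  class(out) <- c("normalized_trajectory", "data.frame")
  out
}

#' Apply the toward/away sign convention
#'
#' Negates the orthogonal coordinate of trials in which the distractor was
#' presented counterclockwise relative to the second-saccade direction. Since
#' the rotated frame places clockwise distractors on the positive-ortho side,
#' this makes positive values mean "toward the distractor's screen position"
#' and negative values "away from it" for every trial.
#'
#' @param traj A `normalized_trajectory` (or any data.frame with `ortho`).
#' @param rotation `"clockwise"` or `"counterclockwise"`.
#' @return The trajectory, with `ortho` negated for counterclockwise trials.
#' @export
apply_sign_convention <- function(traj, rotation) {
  rotation <- match.arg(rotation, c("clockwise", "counterclockwise"))
  if (rotation == "counterclockwise") traj$ortho <- -traj$ortho
  traj
}

#' Saccade curvature angle
#'
#' The scalar curvature statistic: the median, over interior points, of the
#' angular deviation of each point from the straight chord connecting the
#' first and last point of the trajectory. For each interior point the
#' deviation angle is `atan(d / a)` where `d` is the perpendicular deviation
#' from the chord and `a` the along-chord distance from the chord start.
#' Points within `margin` (as a fraction of the chord length) of either chord
#' end are excluded, because the deviation angle is numerically unstable near
#' the start point.
#'
#' With the sign convention of [apply_sign_convention()], negative angles mean
#' curvature away from the distractor's screen position and positive angles
#' curvature toward it. The result always lies strictly within (-90, 90).
#'
#' @param traj A data.frame with columns `grid` (or `along`) and `ortho`,
#'   ordered along the movement, including the endpoints.
#' @param margin Fraction of the chord excluded at each end (default 0.05).
#' @return The curvature angle in degrees (single numeric value).
#' @export
#' @examples
#' traj <- data.frame(grid = c(0, 2.5, 5, 7.5, 10),
#'                    ortho = c(0, 0.5, 1, 0.5, 0))
#' curvature_angle(traj) # 11.31: median of atan(.5/2.5), atan(1/5), atan(.5/7.5)
curvature_angle <- function(traj, margin = 0.05) {
  g <- if ("grid" %in% names(traj)) traj$grid else traj$along
  o <- traj$ortho
  n <- length(g)
  if (n < 5) stop("curvature_angle needs at least 5 points", call. = FALSE)
  cx <- g[n] - g[1]
  cy <- o[n] - o[1]
  len <- sqrt(cx^2 + cy^2)
  if (len < 1e-9) stop("degenerate chord: start and end coincide",
                       call. = FALSE)
  ux <- cx / len
  uy <- cy / len
  dg <- g - g[1]
  do <- o - o[1]
  a <- dg * ux + do * uy        # along-chord distance from start
  d <- do * ux - dg * uy        # perpendicular deviation, positive = +ortho side
  interior <- seq_len(n) != 1L & seq_len(n) != n &
    a / len > margin & a / len < 1 - margin
  if (sum(interior) < 3) {
    stop("curvature_angle needs at least 3 interior points", call. = FALSE)
  }
  stats::median(atan2(d[interior], a[interior])) * 180 / pi
}

# internal: curvature of a raw xy path through the standard chain
# (rotate into the start->end frame, monotonic resample, curvature statistic)
path_curvature <- function(path, n_bins = 50, margin = 0.05) {
  n <- nrow(path)
  start <- c(path$x_deg[1], path$y_deg[1])
  endp <- c(path$x_deg[n], path$y_deg[n])
  u <- endp - start
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate path", call. = FALSE)
  u <- u / nu
  n_right <- c(u[2], -u[1])
  dx <- path$x_deg - start[1]
  dy <- path$y_deg - start[2]
  rot <- data.frame(along = dx * u[1] + dy * u[2],
                    ortho = dx * n_right[1] + dy * n_right[2])
  attr(rot, "amplitude") <- rot$along[nrow(rot)]
  curvature_angle(monotonic_resample(rot, n_bins = n_bins), margin = margin)
}
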