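# Saccade path construction: straight transport along the start->end axis with
# a single orthogonal "bump", scaled so that the standard curvature statistic
# of the noiseless path equals a requested angle.

# internal: raised-cosine along-axis progress, u in [0,1] -> s in [0,1]
# (integral of the raised-cosine speed profile; smooth, main-sequence-like)
raised_cosine_progress <- function(u) {
  u - sin(2 * pi * u) / (2 * pi)
}

# environment caching curvature->bump-height calibrations per geometry
.calibration_cache <- new.env(parent = emptyenv())

# internal: inverse map from requested curvature angle (deg) to the height of
# the sin(pi*s) orthogonal bump, for a saccade of given amplitude/duration.
# The map is built by evaluating the pipeline's own statistic (monotonic
# resampling then median angular deviation) on a grid of bump heights and
# inverting the monotone relation with a Hyman spline. Vectorized over
# `curvature_deg`; odd in its argument.
bump_height_for_curvature <- function(curvature_deg, amplitude, duration,
                                      rate = 1000, n_bins = 50,
                                      margin = 0.05) {
  key <- paste(signif(amplitude, 10), signif(duration, 10), rate, n_bins,
               margin, sep = "|")
  inv <- .calibration_cache[[key]]
  if (is.null(inv)) {
    dt <- 1000 / rate
    t <- seq(0, duration, by = dt)
    s <- raised_cosine_progress(t / duration)
    rot0 <- data.frame(along = s * amplitude, ortho = sin(pi * s))
    attr(rot0, "amplitude") <- amplitude
    shape <- monotonic_resample(rot0, n_bins = n_bins) # linear in bump height
    h_grid <- seq(0, 2 * amplitude, length.out = 241)
    ang <- vapply(h_grid, function(h) {
      prof <- data.frame(grid = shape$grid, ortho = h * shape$ortho)
      curvature_angle(prof, margin = margin)
    }, numeric(1))
    inv <- stats::splinefun(ang, h_grid, method = "hyman")
    attr(inv, "max_angle") <- ang[length(ang)]
    .calibration_cache[[key]] <- inv
  }
  if (any(abs(curvature_deg) > attr(inv, "max_angle"))) {
    stop(sprintf("requested curvature exceeds the calibrated range (+/-%.1f deg)",
                 attr(inv, "max_angle")), call. = FALSE)
  }
  sign(curvature_deg) * inv(abs(curvature_deg))
}

#' Generate a curved saccade path
#'
#' Builds a noiseless saccadic gaze path from `start` to `end` with a
#' raised-cosine speed profile and a single orthogonal deviation bump
#' (`sin(pi * s)` of the normalized along-axis progress `s`), scaled so that
#' the curvature-angle statistic ([curvature_angle()], computed on the
#' monotonically resampled path) equals `curvature_deg` to within a few
#' thousandths of a degree. Positive `curvature_deg` deviates the path toward
#' the right-hand (clockwise) side of the direction of motion; along-path
#' progress is monotonic by construction.
#'
#' @param start,end Numeric length-2 vectors (x, y) in degrees.
#' @param curvature_deg Requested curvature angle (deg).
#' @param duration Saccade duration in ms (at least 10).
#' @param rate Sampling rate in Hz.
#' @param n_bins,margin Parameters of the reference curvature statistic used
#'   for calibration; keep at the analysis defaults.
#' @return A data.frame with columns `t_ms`, `x_deg`, `y_deg`, one row per
#'   sample, from `t = 0` (at `start`) to `t = duration` (at `end`).
#' @export
#' @examples
#' path <- curved_saccade_path(c(0, 0), c(0, 15), curvature_deg = 5,
#'                             duration = 54)
curved_saccade_path <- function(start, end, curvature_deg, duration,
                                rate = 1000, n_bins = 50, margin = 0.05) {
  stopifnot(length(start) == 2, length(end) == 2)
  if (duration < 10) stop("saccade duration must be at least 10 ms",
                          call. = FALSE)
  amplitude <- sqrt(sum((end - start)^2))
  if (amplitude < 1e-9) {
    stop("zero-amplitude saccade: start and end coincide", call. = FALSE)
  }
  u <- (end - start) / amplitude
  n_right <- c(u[2], -u[1])
  h <- bump_height_for_curvature(curvature_deg, amplitude, duration, rate,
                                 n_bins, margin)
  t <- seq(0, duration, by = 1000 / rate)
  s <- raised_cosine_progress(t / duration)
  bump <- h * sin(pi * s)
  data.frame(
    t_ms = t,
    x_deg = start[1] + s * amplitude * u[1] + bump * n_right[1],
    y_deg = start[2] + s * amplitude * u[2] + bump * n_right[2]
  )
}
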