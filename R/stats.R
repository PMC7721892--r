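# Condition summaries and hierarchical bootstrap inference.
#
# Per-trial curvature angles are aggregated to participant means, then to a
# group mean with SEM over participants. Statistical comparisons resample
# trials with replacement within each participant (preserving the participant
# and condition structure), form participant means and a group mean per
# replicate, and derive two-tailed p-values from the distribution of
# replicate differences.

#' Summarize a condition
#'
#' Aggregates per-trial curvature angles of one condition: participant mean
#' over trials, then group mean and SEM (SD of participant means divided by
#' the square root of the number of participants).
#'
#' @param results Data.frame with columns `participant` and `value` (or
#'   `curvature_deg`).
#' @return One-row data.frame: `n_participants`, `n_trials`, `mean`, `sem`
#'   (`NA` with a warning flag attribute for a single participant).
#' @export
summarize_condition <- function(results) {
  v <- if ("value" %in% names(results)) results$value else results$curvature_deg
  if (length(v) == 0) stop("empty condition", call. = FALSE)
  pm <- tapply(v, results$participant, mean)
  n_p <- length(pm)
  out <- data.frame(
    n_participants = n_p,
    n_trials = length(v),
    mean = mean(pm),
    sem = if (n_p >= 2) stats::sd(pm) / sqrt(n_p) else NA_real_
  )
  attr(out, "single_participant") <- n_p < 2
  out
}

#' Hierarchical bootstrap distribution of a condition mean
#'
#' Draws `n_boot` bootstrap replicates of the group mean: in each replicate,
#' every participant's trials are resampled with replacement (keeping that
#' participant's trial count), participant means are formed, and their mean
#' across participants is one replicate. This keeps the participant and
#' condition structure of the original data. `level = "participant"` instead
#' resamples participant means with replacement across participants.
#'
#' @param results Data.frame with columns `participant` and `value` (or
#'   `curvature_deg`).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed; the replicate vector is then
#'   reproducible and the caller's RNG state is left untouched.
#' @param level `"trial"` (hierarchical, default) or `"participant"`.
#'
#' @return An object of class `curvature_bootstrap`: list with `boot` (the
#'   `n_boot` replicate group means), `observed_mean`, `n_boot`, `seed`,
#'   `n_participants`, `n_trials`, `level`.
#' @export
bootstrap_distribution <- function(results, n_boot = 10000, seed = NULL,
                                   level = c("trial", "participant")) {
  level <- match.arg(level)
  if (n_boot <= 0) stop("n_boot must be strictly positive", call. = FALSE)
  v <- if ("value" %in% names(results)) results$value else results$curvature_deg
  if (length(v) == 0) stop("empty condition", call. = FALSE)
  by_p <- split(v, results$participant)
  n_p <- length(by_p)
  if (n_p < 2) stop("bootstrap inference needs at least 2 participants",
                    call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  pmeans <- vapply(by_p, mean, numeric(1))
  if (level == "participant") {
    idx <- matrix(sample.int(n_p, n_p * n_boot, replace = TRUE), nrow = n_p)
    boot <- colMeans(matrix(pmeans[idx], nrow = n_p))
  } else {
    acc <- numeric(n_boot)
    for (p in seq_len(n_p)) {
      vp <- by_p[[p]]
      np <- length(vp)
      idx <- sample.int(np, np * n_boot, replace = TRUE)
      acc <- acc + colMeans(matrix(vp[idx], nrow = np))
    }
    boot <- acc / n_p
  }
  structure(
    list(boot = boot, observed_mean = mean(pmeans), n_boot = as.integer(n_boot),
         seed = seed, n_participants = n_p, n_trials = length(v),
         level = level),
    class = "curvature_bootstrap"
  )
}

#' @export
print.curvature_bootstrap <- function(x, ...) {
  cat(sprintf("<curvature_bootstrap> %d replicates, %d participants, %d trials\n",
              x$n_boot, x$n_participants, x$n_trials))
  cat(sprintf("  observed mean %.3f, replicate SD %.3f\n",
              x$observed_mean, stats::sd(x$boot)))
  invisible(x)
}

#' Two-tailed bootstrap p-value for a condition difference
#'
#' Subtracts the bootstrap replicates of condition `a` from those of
#' condition `b` elementwise and derives a two-tailed p-value from the
#' distribution of the differences:
#' `p = 2 * min(fraction(d >= 0), fraction(d <= 0))`, floored at
#' `2 / (n_boot + 1)` to avoid zero p-values from finite resampling.
#'
#' @param a,b `curvature_bootstrap` objects with equal `n_boot`.
#' @return The two-tailed p-value (a probability in (0, 1]).
#' @export
two_tailed_p <- function(a, b) {
  stopifnot(inherits(a, "curvature_bootstrap"),
            inherits(b, "curvature_bootstrap"))
  if (a$n_boot != b$n_boot) {
    stop("bootstrap distributions have different n_boot", call. = FALSE)
  }
  d <- b$boot - a$boot
  p <- 2 * min(mean(d >= 0), mean(d <= 0))
  min(max(p, 2 / (a$n_boot + 1)), 1)
}

#' Median split of first-saccade latencies
#'
#' Assigns each trial to an `"early"` or `"late"` group relative to the
#' participant's own median first-saccade latency: strictly below the median
#' is early, strictly above is late, and trials at the median alternate
#' between the groups (starting with the smaller one) so that group sizes
#' differ by at most one per participant.
#'
#' @param results Data.frame with columns `participant` and `latency` (ms);
#'   any other columns are preserved.
#' @return The input with an added `latency_group` column.
#' @export
median_split_latency <- function(results) {
  split_one <- function(lat) {
    med <- stats::median(lat)
    grp <- ifelse(lat < med, "early", ifelse(lat > med, "late", NA))
    ties <- which(is.na(grp))
    n_e <- sum(grp == "early", na.rm = TRUE)
    n_l <- sum(grp == "late", na.rm = TRUE)
    for (i in ties) {
      if (n_e <= n_l) {
        grp[i] <- "early"; n_e <- n_e + 1
      } else {
        grp[i] <- "late"; n_l <- n_l + 1
      }
    }
    grp
  }
  groups <- unsplit(lapply(split(results$latency, results$participant),
                           split_one),
                    results$participant)
  results$latency_group <- groups
  results
}
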