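# End-to-end pipeline: configuration, delimited-text readers/writers, the
# table-level stage drivers, condition summaries/comparisons and the run
# manifest.

#' Pipeline configuration
#'
#' Bundles every analysis parameter in one object that round-trips losslessly
#' through its YAML file representation. Defaults are the standard parameters
#' of the double-step distractor paradigm: 3.5 deg control radii, 20-sample
#' velocity smoothing with a 3 SD threshold held for 20 ms, 150 ms
#' pre-saccadic and 100 ms inter-saccadic windows, 50 resampling bins, and
#' 10,000 bootstrap replicates.
#'
#' @param simulation A [simulation_config()] (used when no input tables are
#'   supplied to [run_pipeline()]).
#' @param detection A [detection_params()].
#' @param selection A [selection_criteria()].
#' @param n_bins Bins for [monotonic_resample()].
#' @param margin Interior-point exclusion margin for [curvature_angle()].
#' @param n_boot Bootstrap replicates for condition comparisons.
#' @param seed Seed for the bootstrap stage (the generator uses
#'   `simulation$seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            detection = detection_params(),
                            selection = selection_criteria(),
                            n_bins = 50, margin = 0.05,
                            n_boot = 10000, seed = 1L) {
  stopifnot(inherits(simulation, "simulation_config"),
            inherits(detection, "detection_params"),
            inherits(selection, "selection_criteria"),
            n_bins >= 10, margin >= 0, margin < 0.5, n_boot > 0)
  structure(
    list(simulation = simulation, detection = detection,
         selection = selection, n_bins = as.integer(n_bins), margin = margin,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# internal: pipeline_config <-> plain nested list (for YAML round-tripping)
.config_to_plain <- function(config) {
  sim <- unclass(config$simulation)
  sim$apparatus <- unclass(sim$apparatus)
  sim$effect_map <- as.list(sim$effect_map)
  sim$latency_model$first <- as.list(sim$latency_model$first)
  sim$latency_model$second <- as.list(sim$latency_model$second)
  list(
    simulation = sim,
    detection = unclass(config$detection),
    selection = unclass(config$selection),
    analysis = list(n_bins = config$n_bins, margin = config$margin,
                    n_boot = config$n_boot, seed = config$seed)
  )
}

.config_from_plain <- function(plain) {
  sim <- plain$simulation
  app <- do.call(apparatus_config, sim$apparatus)
  em <- as.data.frame(sim$effect_map, stringsAsFactors = FALSE)
  lm <- sim$latency_model
  lm$first <- unlist(lm$first)
  lm$second <- unlist(lm$second)
  sim_args <- sim[setdiff(names(sim), c("apparatus", "effect_map",
                                        "latency_model"))]
  sim_args$distractor_onset_range <- unlist(sim_args$distractor_onset_range)
  sim_cfg <- do.call(simulation_config,
                     c(sim_args, list(apparatus = app, effect_map = em,
                                      latency_model = lm)))
  pipeline_config(
    simulation = sim_cfg,
    detection = do.call(detection_params, plain$detection),
    selection = do.call(selection_criteria, plain$selection),
    n_bins = plain$analysis$n_bins, margin = plain$analysis$margin,
    n_boot = plain$analysis$n_boot, seed = plain$analysis$seed
  )
}

#' Write / read a pipeline configuration file
#'
#' The configuration is stored as YAML; reading reconstructs an identical
#' [pipeline_config()] object.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(yaml::as.yaml(.config_to_plain(config), precision = 15), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  .config_from_plain(yaml::read_yaml(path))
}

# internal: validate a freshly read table against a column schema
.check_schema <- function(dt, numeric_cols, character_cols, path) {
  missing <- setdiff(c(numeric_cols, character_cols), names(dt))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    val <- dt[[col]]
    if (!is.numeric(val)) {
      chr <- as.character(val)
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(!is.na(chr) & chr != "" & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("%s: non-numeric value in column '%s' at data row(s) %s",
                     path, col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      data.table::set(dt, j = col, value = num)
    }
  }
  dt
}

#' Read and write pipeline tables
#'
#' Delimited-text (CSV) readers and writers for the pipeline's tables. Column
#' order is irrelevant (header-keyed); malformed numeric values are rejected
#' with the offending column and row reported. In gaze tables, empty
#' position fields (tracker dropout during blinks) become missing values and
#' are written back as empty fields.
#'
#' @param path File path.
#' @return Readers return a `data.table`; writers return `path` invisibly.
#' @export
read_gaze_table <- function(path) {
  dt <- data.table::fread(path, na.strings = c("", "NA"))
  .check_schema(dt, c("trial_id", "t_ms", "x_deg", "y_deg"), character(0),
                path)
  dt[, c("trial_id", "t_ms", "x_deg", "y_deg")]
}

#' @rdname read_gaze_table
#' @export
read_events_table <- function(path) {
  dt <- data.table::fread(path, na.strings = c("", "NA"))
  .check_schema(
    dt,
    c("trial_id", "participant", "distractor_x_deg", "distractor_y_deg",
      "distractor_onset_ms", "distractor_duration_ms"),
    c("fixation_side", "target2_dir", "distractor_modality"),
    path
  )
  bad_side <- !dt$fixation_side %in% c("left", "right")
  if (any(bad_side)) {
    stop(sprintf("%s: invalid fixation_side at data row(s) %s", path,
                 paste(utils::head(which(bad_side), 5), collapse = ", ")),
         call. = FALSE)
  }
  dt
}

#' @rdname read_gaze_table
#' @param x Table to write.
#' @export
write_gaze_table <- function(x, path) {
  data.table::fwrite(x, path, na = "")
  invisible(path)
}

#' @rdname read_gaze_table
#' @export
write_table <- function(x, path) {
  data.table::fwrite(x, path, na = "")
  invisible(path)
}

#' Detect saccades in a multi-trial gaze table
#'
#' Runs [compute_velocity()] and [detect_saccades()] on every trial of a gaze
#' table.
#'
#' @param gaze Gaze table (`trial_id`, `t_ms`, `x_deg`, `y_deg`).
#' @param params A [detection_params()].
#' @return A `data.table` of saccades with `trial_id` and `index` columns.
#' @export
detect_saccades_table <- function(gaze, params = detection_params()) {
  gaze <- data.table::as.data.table(gaze)
  trial_id <- t_ms <- NULL # data.table NSE
  out <- gaze[order(trial_id, t_ms),
              {
                vel <- compute_velocity(.SD, params)
                s <- detect_saccades(vel, params, trace = .SD)
                if (nrow(s) > 0) s$index <- seq_len(nrow(s))
                s
              },
              by = trial_id]
  out
}

#' Select and classify all trials
#'
#' Applies [assign_sequence()], [validate_trial()] and the interval/hemifield/
#' rotation classifiers to every trial, producing the trial-level table the
#' curvature stage consumes.
#'
#' @param gaze Gaze table.
#' @param events Events table (one row per trial).
#' @param saccades Output of [detect_saccades_table()].
#' @param criteria A [selection_criteria()].
#' @param apparatus An [apparatus_config()].
#' @return A `data.table`, one row per trial: identifiers, condition columns,
#'   `valid`, `reason`, `interval`, `hemifield`, `rotation`, first/second
#'   saccade onsets/offsets/latencies and second-saccade start position.
#' @export
classify_trials_table <- function(gaze, events, saccades,
                                  criteria = selection_criteria(),
                                  apparatus = apparatus_config()) {
  gaze <- data.table::as.data.table(gaze)
  events <- data.table::as.data.table(events)
  trial_id <- t_ms <- x_deg <- y_deg <- NULL # data.table NSE

  blink_dt <- gaze[, list(has_blink = anyNA(x_deg) || anyNA(y_deg)),
                   by = trial_id]
  ecc <- apparatus$target_eccentricity
  ev_fix_x <- ifelse(events$fixation_side == "right", ecc, -ecc)
  fix_x_of <- stats::setNames(ev_fix_x, events$trial_id)
  hold <- gaze[t_ms >= -criteria$hold_duration & t_ms < 0]
  hold_dt <- hold[, {
    fx <- fix_x_of[as.character(trial_id[1])]
    list(fixation_held = all(.dist2(x_deg, y_deg, fx, 0) <=
                               criteria$fixation_radius, na.rm = TRUE))
  }, by = trial_id]

  has_blink <- stats::setNames(blink_dt$has_blink, blink_dt$trial_id)
  fixation_held <- stats::setNames(hold_dt$fixation_held, hold_dt$trial_id)
  sacc_split <- split(as.data.frame(saccades), saccades$trial_id)
  no_sacc <- .fast_df(list(onset_t = numeric(0), x0 = numeric(0),
                           y0 = numeric(0), x1 = numeric(0),
                           y1 = numeric(0), amplitude = numeric(0)))

  ev_trial <- events$trial_id
  ev_part <- events$participant
  ev_side <- events$fixation_side
  ev_t2 <- events$target2_dir
  ev_mod <- events$distractor_modality
  ev_dx <- events$distractor_x_deg
  ev_dy <- events$distractor_y_deg
  ev_don <- events$distractor_onset_ms
  ev_ddur <- events$distractor_duration_ms

  n <- nrow(events)
  na_n <- rep(NA_real_, n)
  out <- list(
    trial_id = ev_trial, participant = ev_part, fixation_side = ev_side,
    target2_dir = ev_t2, modality = ev_mod,
    valid = rep(FALSE, n), reason = rep(NA_character_, n),
    interval = rep(NA_character_, n),
    hemifield = rep("not_applicable", n), rotation = rep("none", n),
    onset1 = na_n, offset1 = na_n, latency1 = na_n,
    onset2 = na_n, offset2 = na_n, latency2 = na_n,
    x0_2 = na_n, y0_2 = na_n
  )
  for (i in seq_len(n)) {
    ev <- list(trial_id = ev_trial[i], participant = ev_part[i],
               fixation_side = ev_side[i], target2_dir = ev_t2[i],
               distractor_modality = ev_mod[i],
               distractor_x_deg = ev_dx[i], distractor_y_deg = ev_dy[i],
               distractor_onset_ms = ev_don[i],
               distractor_duration_ms = ev_ddur[i])
    key <- as.character(ev_trial[i])
    s_i <- sacc_split[[key]]
    if (is.null(s_i)) s_i <- no_sacc
    assignment <- assign_sequence(s_i, ev, apparatus)
    cls <- classify_trial(ev, assignment, criteria, apparatus,
                          has_blink = isTRUE(has_blink[[key]]),
                          fixation_held = isTRUE(fixation_held[[key]]))
    out$valid[i] <- cls$valid
    out$reason[i] <- cls$reason
    out$interval[i] <- cls$interval
    out$hemifield[i] <- cls$hemifield
    out$rotation[i] <- cls$rotation
    if (assignment$valid) {
      out$onset1[i] <- assignment$first$onset_t
      out$offset1[i] <- assignment$first$offset_t
      out$latency1[i] <- assignment$first$latency
      out$onset2[i] <- assignment$second$onset_t
      out$offset2[i] <- assignment$second$offset_t
      out$latency2[i] <- assignment$second$latency
      out$x0_2[i] <- assignment$second$x0
      out$y0_2[i] <- assignment$second$y0
    }
  }
  data.table::as.data.table(out)
}

#' Compute normalized per-trial curvature angles
#'
#' For every valid trial whose distractor interval is pre-saccadic,
#' inter-saccadic or distractor-absent: rotates the second saccade into the
#' saccade-direction frame, resamples it onto the monotonic grid, subtracts
#' the participant- and sequence-specific mean profile of distractor-absent
#' trials, applies the toward/away sign convention and computes the
#' curvature angle.
#'
#' @param gaze Gaze table.
#' @param trials Output of [classify_trials_table()].
#' @param n_bins,margin Analysis parameters (see [pipeline_config()]).
#' @param apparatus An [apparatus_config()].
#' @return A `data.table`, one row per analyzed trial: identifiers, condition
#'   columns, latencies, `curvature_deg` and `baseline_n` (number of
#'   distractor-absent trials behind the subtracted baseline).
#' @export
compute_curvature_table <- function(gaze, trials, n_bins = 50, margin = 0.05,
                                    apparatus = apparatus_config()) {
  gaze <- data.table::as.data.table(gaze)
  trials <- data.table::as.data.table(trials)
  valid <- interval <- NULL # data.table NSE
  ana <- trials[valid & interval %in% c("pre_saccadic", "inter_saccadic",
                                        "no_distractor")]
  if (nrow(ana) == 0) stop("no analyzable trials", call. = FALSE)

  # extract second-saccade samples of analyzed trials
  w <- match(gaze$trial_id, ana$trial_id)
  keep <- !is.na(w) & gaze$t_ms >= ana$onset2[w] & gaze$t_ms <= ana$offset2[w]
  samples <- gaze[keep]
  samples_split <- split(as.data.frame(samples), samples$trial_id)

  n_ana <- nrow(ana)
  prof <- matrix(NA_real_, n_ana, n_bins)
  amp <- rep(NA_real_, n_ana)
  ok <- rep(FALSE, n_ana)
  for (i in seq_len(n_ana)) {
    tr <- samples_split[[as.character(ana$trial_id[i])]]
    second <- list(onset_t = ana$onset2[i], offset_t = ana$offset2[i],
                   x0 = ana$x0_2[i], y0 = ana$y0_2[i])
    ev <- list(target2_dir = ana$target2_dir[i])
    res <- try({
      rot <- rotate_to_upward(second, tr, ev, apparatus)
      monotonic_resample(rot, n_bins = n_bins)
    }, silent = TRUE)
    if (!inherits(res, "try-error")) {
      prof[i, ] <- res$ortho
      amp[i] <- attr(res, "amplitude")
      ok[i] <- TRUE
    }
  }

  # baselines: mean profile of distractor-absent trials per participant x
  # saccade sequence
  seq_key <- paste(ana$participant, ana$fixation_side, ana$target2_dir,
                   sep = "|")
  is_base <- ana$interval == "no_distractor" & ok
  base_keys <- unique(seq_key[is_base])
  base_prof <- lapply(base_keys, function(k) {
    rows <- which(is_base & seq_key == k)
    list(ortho = colMeans(prof[rows, , drop = FALSE]),
         amplitude = mean(amp[rows]), n = length(rows))
  })
  names(base_prof) <- base_keys

  curvature <- rep(NA_real_, n_ana)
  baseline_n <- rep(0L, n_ana)
  for (i in which(ok)) {
    b <- base_prof[[seq_key[i]]]
    if (is.null(b)) next
    grid_i <- (seq_len(n_bins) - 0.5) * amp[i] / n_bins
    grid_b <- (seq_len(n_bins) - 0.5) * b$amplitude / n_bins
    b_ortho <- if (abs(b$amplitude - amp[i]) < 1e-9) b$ortho else {
      stats::approx(grid_b, b$ortho, xout = grid_i, rule = 2)$y
    }
    traj <- data.frame(grid = grid_i, ortho = prof[i, ] - b_ortho)
    if (identical(ana$rotation[i], "counterclockwise")) {
      traj <- apply_sign_convention(traj, "counterclockwise")
    }
    curvature[i] <- curvature_angle(traj, margin = margin)
    baseline_n[i] <- b$n
  }

  out <- data.table::data.table(
    trial_id = ana$trial_id, participant = ana$participant,
    fixation_side = ana$fixation_side, target2_dir = ana$target2_dir,
    modality = ana$modality, interval = ana$interval,
    hemifield = ana$hemifield, rotation = ana$rotation,
    latency1 = ana$latency1, latency2 = ana$latency2,
    curvature_deg = curvature, baseline_n = baseline_n
  )
  out[!is.na(out$curvature_deg)]
}

# internal: canonical condition label
.condition_label <- function(modality, interval, hemifield) {
  ifelse(interval == "no_distractor", "no_distractor",
         ifelse(interval == "inter_saccadic",
                paste(modality, "inter_saccadic", sep = "."),
                paste(modality, "pre_saccadic", hemifield, sep = ".")))
}

#' Summarize curvature by condition
#'
#' Participant-then-group aggregation of per-trial curvature angles for every
#' condition (modality x interval, with pre-saccadic trials split by
#' hemifield). Optionally splits pre-saccadic conditions further by a
#' per-participant median split of first-saccade latencies.
#'
#' @param results Output of [compute_curvature_table()].
#' @param split_latency If `TRUE`, adds early/late rows for pre-saccadic
#'   conditions.
#' @return A `data.table`: `condition`, `modality`, `interval`, `hemifield`,
#'   (`latency_group`,) `n_participants`, `n_trials`, `mean`, `sem`.
#' @export
summarize_conditions <- function(results, split_latency = FALSE) {
  results <- data.table::as.data.table(results)
  results$condition <- .condition_label(results$modality, results$interval,
                                        results$hemifield)
  summ <- function(df, extra = list()) {
    s <- summarize_condition(df)
    data.table::as.data.table(
      c(list(condition = df$condition[1], modality = df$modality[1],
             interval = df$interval[1], hemifield = df$hemifield[1]),
        extra, as.list(s))
    )
  }
  parts <- lapply(split(as.data.frame(results), results$condition), summ)
  out <- data.table::rbindlist(parts)
  if (split_latency) {
    pre <- results[results$interval == "pre_saccadic"]
    pre$latency <- pre$latency1
    pre <- median_split_latency(as.data.frame(pre))
    key <- paste(pre$condition, pre$latency_group)
    lat_parts <- lapply(split(pre, key), function(df) {
      summ(df, extra = list(latency_group = df$latency_group[1]))
    })
    lat <- data.table::rbindlist(lat_parts)
    out$latency_group <- "all"
    out <- data.table::rbindlist(list(out, lat), use.names = TRUE)
  }
  out[order(out$condition)]
}

#' Bootstrap comparisons of distractor conditions against no-distractor
#'
#' Builds the hierarchical bootstrap distribution of every condition and of
#' the distractor-absent condition, and derives two-tailed p-values for each
#' condition-vs-no-distractor difference (the same differencing scheme is
#' used for condition-vs-condition comparisons via [two_tailed_p()]).
#'
#' @param results Output of [compute_curvature_table()].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed; comparison `i` uses `seed + i`.
#' @return A `data.table`: `condition_a`, `condition_b`, `mean_a`, `mean_b`,
#'   `mean_diff`, `p_two_tailed`, `n_boot`, `seed`.
#' @export
compare_conditions <- function(results, n_boot = 10000, seed = 1L) {
  results <- data.table::as.data.table(results)
  results$condition <- .condition_label(results$modality, results$interval,
                                        results$hemifield)
  results$value <- results$curvature_deg
  conds <- setdiff(sort(unique(results$condition)), "no_distractor")
  none <- results[results$condition == "no_distractor"]
  if (nrow(none) == 0) stop("no distractor-absent trials to compare against",
                            call. = FALSE)
  boot_none <- bootstrap_distribution(none, n_boot, seed = seed)
  rows <- lapply(seq_along(conds), function(i) {
    df <- results[results$condition == conds[i]]
    b <- bootstrap_distribution(df, n_boot, seed = seed + i)
    data.table::data.table(
      condition_a = "no_distractor", condition_b = conds[i],
      mean_a = boot_none$observed_mean, mean_b = b$observed_mean,
      mean_diff = b$observed_mean - boot_none$observed_mean,
      p_two_tailed = two_tailed_p(boot_none, b),
      n_boot = as.integer(n_boot), seed = as.integer(seed + i)
    )
  })
  data.table::rbindlist(rows)
}

#' Run the full pipeline
#'
#' Simulation (or supplied tables) -> saccade detection -> trial selection and
#' classification -> normalized trajectory curvature -> condition summaries
#' and bootstrap comparisons, with a run manifest reconciling trial counts at
#' every stage. Deterministic given the configuration and its seeds.
#'
#' @param config A [pipeline_config()].
#' @param gaze,events Optional input tables; when `NULL`, a synthetic
#'   experiment is generated from `config$simulation`.
#' @param output_dir Optional directory; when given, all intermediate and
#'   final tables, the configuration and the manifest are written there.
#' @return A list of class `saccurv_run`: `trials` (per-trial curvature),
#'   `classification`, `summary`, `comparisons`, `manifest`, and `truth`
#'   (ground truth, simulated inputs only).
#' @export
run_pipeline <- function(config = pipeline_config(), gaze = NULL,
                         events = NULL, output_dir = NULL) {
  truth <- NULL
  if (is.null(gaze) || is.null(events)) {
    sim <- simulate_experiment(config$simulation)
    gaze <- sim$gaze
    events <- sim$events
    truth <- sim$truth
  }
  apparatus <- config$simulation$apparatus
  saccades <- detect_saccades_table(gaze, config$detection)
  classification <- classify_trials_table(gaze, events, saccades,
                                          config$selection, apparatus)
  results <- compute_curvature_table(gaze, classification, config$n_bins,
                                     config$margin, apparatus)
  summary <- summarize_conditions(results, split_latency = TRUE)
  comparisons <- compare_conditions(results, config$n_boot, config$seed)

  reason_counts <- table(classification$reason[!classification$valid])
  interval_counts <- table(classification$interval[classification$valid])
  cfg_file <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("saccurv")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = list(simulation = config$simulation$seed,
                 bootstrap = config$seed),
    counts = list(
      trials_in = nrow(events),
      gaze_samples = nrow(gaze),
      saccades_detected = nrow(saccades),
      trials_valid = sum(classification$valid),
      trials_rejected = sum(!classification$valid),
      rejected_by_reason = as.list(reason_counts),
      valid_by_interval = as.list(interval_counts),
      trials_analyzed = nrow(results)
    )
  )
  unlink(cfg_file)
  stopifnot(manifest$counts$trials_in ==
              manifest$counts$trials_valid + manifest$counts$trials_rejected)

  out <- structure(
    list(trials = results, classification = classification,
         summary = summary, comparisons = comparisons, manifest = manifest,
         truth = truth),
    class = "saccurv_run"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(results, file.path(output_dir, "trial_curvature.csv"))
    write_table(classification, file.path(output_dir, "classification.csv"))
    write_table(summary, file.path(output_dir, "summary.csv"))
    write_table(comparisons, file.path(output_dir, "comparisons.csv"))
    write_pipeline_config(config, file.path(output_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.saccurv_run <- function(x, ...) {
  cat("<saccurv_run>\n")
  cat(sprintf("  %d trials in, %d valid, %d analyzed\n",
              x$manifest$counts$trials_in, x$manifest$counts$trials_valid,
              x$manifest$counts$trials_analyzed))
  print(x$summary[x$summary$latency_group == "all",
                  c("condition", "n_trials", "mean", "sem")])
  invisible(x)
}
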