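#' Analysis run configuration
#'
#' Bundles every tunable of the processing chain with the protocol defaults:
#' filter cut-offs (20 Hz torque, 6 Hz crank angle, 20-400 Hz + 10 Hz EMG),
#' onset detector parameters, hold-window policy, and validity rules.
#'
#' @param experiment 1 or 2.
#' @param torque_cutoff,angle_cutoff,emg_smooth_cutoff desired low-pass
#'   cut-offs, Hz.
#' @param emg_band EMG band-pass edges, Hz.
#' @param onset_threshold onset threshold, %% MVT.
#' @param onset_sustain sustained supra-threshold duration, s.
#' @param window_policy hold-window policy, see [hold_windows()].
#' @param guard guard after each hold boundary, s.
#' @param rules a [validity_rules()].
#' @param fascicle_smooth_cutoff smoothing cut-off for the fascicle
#'   derivative, Hz.
#' @param alpha significance level passed to the statistics layer.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = 1, torque_cutoff = 20, angle_cutoff = 6,
                       emg_band = c(20, 400), emg_smooth_cutoff = 10,
                       onset_threshold = 1, onset_sustain = 0.1,
                       window_policy = "solved", guard = 0.25,
                       rules = validity_rules(experiment),
                       fascicle_smooth_cutoff = 5, alpha = 0.05) {
  structure(list(experiment = experiment, torque_cutoff = torque_cutoff,
                 angle_cutoff = angle_cutoff, emg_band = emg_band,
                 emg_smooth_cutoff = emg_smooth_cutoff,
                 onset_threshold = onset_threshold,
                 onset_sustain = onset_sustain,
                 window_policy = window_policy, guard = guard,
                 rules = rules,
                 fascicle_smooth_cutoff = fascicle_smooth_cutoff,
                 alpha = alpha),
            class = "run_config")
}

#' Build the normalization context from an MVC trial
#'
#' Filters the recorded torque (20 Hz), estimates the pre-onset baseline
#' over the experiment's MVC window (0.5 s in Experiment 1, 0.25 s in
#' Experiment 2), extracts the EMG envelope, and takes the 0.5-s
#' peak-window means of both as the MVT and 100%%-MVC references.
#'
#' @param mvc a trial (from [simulate_trial()] or [read_trial()]) with
#'   condition `"MVC"`.
#' @param config a [run_config()].
#' @return A [normalization_context()]; its `mvt` field carries attribute
#'   `onset`.
#' @export
process_mvc <- function(mvc, config = run_config()) {
  ft <- dual_pass_butterworth(mvc$channels$torque,
                              filter_spec("low-pass", config$torque_cutoff))
  window <- if (config$experiment == 1) 0.5 else 0.25
  bl0 <- mean(ft$values[channel_times(ft) < ft$t0 + window])
  rel <- channel_with(ft, 100 * (ft$values - bl0) / max(ft$values - bl0))
  onset <- detect_contraction_onset(rel, config$onset_threshold,
                                    config$onset_sustain)
  bl <- baseline_torque(ft, onset, window)
  act <- active_torque(ft, bl)
  if (!is.null(mvc$channels$emg)) {
    env <- emg_envelope(mvc$channels$emg, config$emg_band,
                        config$emg_smooth_cutoff)
    ctx <- normalization_context(act, env)
  } else {
    ctx <- structure(list(mvt = peak_window_mean(act, 0.5),
                          mvc_emg_amplitude = NA_real_, mvc_window = 0.5),
                     class = "normalization_context")
  }
  attr(ctx, "onset") <- onset
  ctx
}

#' Process one submaximal trial into its metrics
#'
#' Executes the full per-trial chain: 20-Hz zero-phase torque filtering; a
#' two-pass baseline estimate (provisional from the first second, refined
#' over the 1 s before the detected onset); active torque and MVC
#' normalization; onset detection; torque-matching error against the
#' condition's designed trace; validity gating; hold-phase means; fascicle
#' amplitudes/rates; and Hold 2 torque steadiness.
#'
#' @param trial a trial with `channels` and `condition`.
#' @param context a [normalization_context()] from [process_mvc()].
#' @param config a [run_config()].
#' @return A [trial_metrics()] with attributes `onset` and `windows`.
#' @export
process_trial <- function(trial, context, config = run_config()) {
  lib <- protocol_library(config$experiment)
  if (!trial$condition %in% names(lib))
    stop("unknown condition '", trial$condition, "'")
  trace <- build_desired_trace(lib[[trial$condition]])

  ft <- dual_pass_butterworth(trial$channels$torque,
                              filter_spec("low-pass", config$torque_cutoff))
  # pass 1: provisional baseline from the first second of the recording
  bl0 <- mean(ft$values[channel_times(ft) < ft$t0 + 1])
  norm0 <- normalize_to_mvc(active_torque(ft, bl0), context, "torque")
  onset <- detect_contraction_onset(norm0, config$onset_threshold,
                                    config$onset_sustain)
  # pass 2: protocol baseline over the 1 s before onset
  bl <- baseline_torque(ft, onset, 1.0)
  act_nm <- active_torque(ft, bl)
  act_pct <- normalize_to_mvc(act_nm, context, "torque")
  onset <- detect_contraction_onset(act_pct, config$onset_threshold,
                                    config$onset_sustain)

  err <- torque_matching_error(act_pct, trace, onset)
  verdict <- validate_trial(err, act_nm, trace, onset, config$rules)
  w <- hold_windows(trace, onset, config$window_policy, config$guard)
  pb <- trace$phase_boundaries

  emg1 <- emg2 <- NA_real_
  if (!is.null(trial$channels$emg)) {
    env <- emg_envelope(trial$channels$emg, config$emg_band,
                        config$emg_smooth_cutoff)
    envn <- normalize_to_mvc(env, context, "emg")
    emg1 <- hold_mean(envn, w$hold1)
    emg2 <- hold_mean(envn, w$hold2)
  }
  l1 <- l2 <- sa <- la_mm <- la_pct <- spd <- NA_real_
  if (!is.null(trial$channels$fascicle)) {
    fa <- trial$channels$fascicle
    l1 <- fascicle_hold_mean(fa, w$hold1)
    l2 <- fascicle_hold_mean(fa, w$hold2)
    sa <- shortening_amplitude(fa, onset, onset + pb[["hold2_start"]])
    la <- lengthening_amplitude(fa, onset + pb[["hold1_end"]],
                                onset + pb[["hold2_start"]])
    la_mm <- la$amplitude_mm; la_pct <- la$amplitude_pct
    spd <- max_lengthening_speed(fa, onset + pb[["hold1_end"]],
                                 onset + pb[["hold2_start"]],
                                 config$fascicle_smooth_cutoff)
  }
  m <- trial_metrics(
    hold1_torque = hold_mean(act_pct, w$hold1),
    hold2_torque = hold_mean(act_pct, w$hold2),
    hold1_emg = emg1, hold2_emg = emg2,
    hold1_length = l1, hold2_length = l2,
    shortening_amplitude = sa, lengthening_amplitude_mm = la_mm,
    lengthening_amplitude_pct = la_pct, max_lengthening_speed = spd,
    steadiness_cv = steadiness_cv(act_nm, w$hold2),
    matching_error = err, verdict = verdict)
  attr(m, "onset") <- onset
  attr(m, "windows") <- w
  m
}

#' Run the whole pipeline over a dataset
#'
#' For every subject: build the normalization context from the MVC trial,
#' process every submaximal trial, gate validity, and average the valid
#' trials of each condition. Every exclusion (invalid trial; condition with
#' zero valid trials; a failing trial) is logged with a machine-readable
#' reason code.
#'
#' @param dataset a `sim_dataset` from [generate_dataset()], a directory
#'   written by [write_dataset()], or any list of subjects with `id`, `mvc`,
#'   `trials`.
#' @param config a [run_config()].
#' @return An object of class `results_bundle`: `trials` (one row per
#'   processed trial), `summary` (subject x condition means over valid
#'   trials), `exclusions`, `contexts` (per-subject MVT and EMG references)
#'   and a `provenance` block (config hash, package version).
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  trial_rows <- list(); excl <- list(); ctxs <- list()
  for (s in dataset) {
    ctx <- process_mvc(s$mvc, config)
    ctxs[[s$id]] <- data.frame(subject = s$id, mvt = ctx$mvt,
                               mvc_emg = ctx$mvc_emg_amplitude)
    for (i in seq_along(s$trials)) {
      tr <- s$trials[[i]]
      m <- tryCatch(process_trial(tr, ctx, config), error = function(e) e)
      if (inherits(m, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          subject = s$id, condition = tr$condition, trial = i,
          reason = "processing_error", detail = conditionMessage(m))
        next
      }
      row <- as.data.frame(m)
      row <- cbind(data.frame(subject = s$id, condition = tr$condition,
                              trial = i), row)
      trial_rows[[length(trial_rows) + 1L]] <- row
      if (!m$verdict$valid)
        excl[[length(excl) + 1L]] <- data.frame(
          subject = s$id, condition = tr$condition, trial = i,
          reason = paste(m$verdict$reasons, collapse = "+"),
          detail = sprintf("matching_error=%.2f%%MVT", m$matching_error))
    }
  }
  trials <- do.call(rbind, trial_rows)
  if (is.null(trials)) stop("no trial could be processed")
  summary_rows <- list()
  for (sid in unique(trials$subject)) {
    for (cond in unique(trials$condition[trials$subject == sid])) {
      sub <- trials[trials$subject == sid & trials$condition == cond &
                      trials$valid, ]
      if (nrow(sub) == 0L) {
        excl[[length(excl) + 1L]] <- data.frame(
          subject = sid, condition = cond, trial = NA,
          reason = "condition_excluded", detail = "zero valid trials")
        next
      }
      means <- as.data.frame(lapply(sub[metric_fields()], mean))
      summary_rows[[length(summary_rows) + 1L]] <-
        cbind(data.frame(subject = sid, condition = cond,
                         n_valid = nrow(sub)), means)
    }
  }
  structure(list(
    trials = trials,
    summary = do.call(rbind, summary_rows),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(subject = character(), condition = character(),
                 trial = integer(), reason = character(),
                 detail = character()),
    contexts = do.call(rbind, ctxs),
    provenance = list(config_hash = config_hash(unclass(config)),
                      experiment = config$experiment,
                      package_version = as.character(
                        utils::packageVersion("steadytorque")))),
    class = "results_bundle")
}

#' Write a results bundle as TSV tables
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trial_metrics.tsv"),
             summary = file.path(dir, "condition_summary.tsv"),
             exclusions = file.path(dir, "exclusions.tsv"))
  utils::write.table(bundle$trials, paths["trials"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$summary, paths["summary"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$exclusions, paths["exclusions"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
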