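#' Protocol specification for one condition
#'
#' Describes the designed (displayed) normalized torque profile of a single
#' condition. Test conditions are trapezoids: ramp up at `ascend_rate` to
#' `hold1_level`, hold, ramp down over `descend_duration` to `hold2_level`,
#' hold until `total_duration`. Reference conditions ramp directly to
#' `hold2_level` and stay there; their hold-phase boundaries are borrowed
#' from the paired test condition(s) so comparisons are time-matched.
#'
#' Hold durations are solved from the total duration: when `hold2_duration`
#' is given (Experiment 2 prints 5, 5.75 and 6.5 s), Hold 1 takes what
#' remains; otherwise (Experiment 1) the remainder is split equally between
#' the two holds, which reproduces the printed Hold 2 range 4.25-5.1 s.
#'
#' @param experiment 1 or 2.
#' @param condition_id condition label, e.g. `"0.25-s"` or `"85-15"`.
#' @param hold1_level,hold2_level plateau levels in %% MVT
#'   (`hold1_level >= hold2_level`).
#' @param descend_duration duration of the descending ramp, seconds.
#' @param ascend_rate ascending ramp rate, %% MVT per second (default 20).
#' @param total_duration trace duration, seconds (13.5 in Experiment 1,
#'   15 in Experiment 2).
#' @param hold2_duration Hold 2 duration in seconds, or `NULL` to solve by
#'   the equal-hold closure.
#' @param trace_band_halfwidth half-width of the displayed feedback band,
#'   %% MVT (3 in Experiment 1, 4 in Experiment 2).
#' @param role `"test"` or `"reference"`.
#' @param boundaries for reference conditions: a list with `hold1` and
#'   `hold2` time windows (seconds from onset) borrowed from the paired test
#'   condition(s); ignored for test conditions.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(experiment, condition_id, hold1_level, hold2_level,
                          descend_duration, ascend_rate = 20,
                          total_duration = if (experiment == 1) 13.5 else 15,
                          hold2_duration = NULL,
                          trace_band_halfwidth = if (experiment == 1) 3 else 4,
                          role = c("test", "reference"), boundaries = NULL) {
  role <- match.arg(role)
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2")
  if (hold1_level < hold2_level) stop("hold1_level must be >= hold2_level")
  if (hold1_level > 100 || hold2_level < 0)
    stop("levels must lie in [0, 100] %MVT")
  if (descend_duration < 0 || ascend_rate <= 0 || trace_band_halfwidth <= 0)
    stop("invalid protocol parameters")
  structure(list(experiment = experiment, condition_id = condition_id,
                 hold1_level = hold1_level, hold2_level = hold2_level,
                 descend_duration = descend_duration,
                 ascend_rate = ascend_rate, total_duration = total_duration,
                 hold2_duration = hold2_duration,
                 trace_band_halfwidth = trace_band_halfwidth,
                 role = role, boundaries = boundaries),
            class = "protocol_spec")
}

#' Build the designed torque trace for a condition
#'
#' @param spec a [protocol_spec()].
#' @return An object of class `desired_trace`: piecewise-linear breakpoints
#'   (`times` in seconds from contraction onset, `levels` in %% MVT), the
#'   phase boundaries (`onset`, `hold1_start`, `hold1_end`, `hold2_start`,
#'   `hold2_end`) and the display-band half-width.
#' @export
build_desired_trace <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (spec$role == "reference") {
    ascend <- spec$hold2_level / spec$ascend_rate
    times <- c(0, ascend, spec$total_duration)
    levels <- c(0, spec$hold2_level, spec$hold2_level)
    if (is.null(spec$boundaries))
      stop("reference condition '", spec$condition_id,
           "' needs time-matched hold boundaries")
    pb <- c(onset = 0,
            hold1_start = spec$boundaries$hold1[1],
            hold1_end = spec$boundaries$hold1[2],
            hold2_start = spec$boundaries$hold2[1],
            hold2_end = spec$boundaries$hold2[2])
  } else {
    ascend <- spec$hold1_level / spec$ascend_rate
    free <- spec$total_duration - ascend - spec$descend_duration
    if (is.null(spec$hold2_duration)) {
      hold1 <- free / 2
      hold2 <- free / 2
    } else {
      hold2 <- spec$hold2_duration
      hold1 <- free - hold2
    }
    if (hold1 < 0 || hold2 < 0)
      stop(sprintf(
        "infeasible protocol '%s': solved hold durations %.3g / %.3g s are negative",
        spec$condition_id, hold1, hold2))
    t1 <- ascend
    t2 <- t1 + hold1
    t3 <- t2 + spec$descend_duration
    t4 <- spec$total_duration
    times <- unique(c(0, t1, t2, t3, t4))
    levels <- c(0, spec$hold1_level, spec$hold1_level, spec$hold2_level,
                spec$hold2_level)[seq_along(times)]
    if (spec$descend_duration == 0)  # degenerate drop: hold1 flows into hold2
      levels <- c(0, spec$hold1_level, spec$hold1_level,
                  spec$hold2_level)[seq_along(times)]
    pb <- c(onset = 0, hold1_start = t1, hold1_end = t2,
            hold2_start = t3, hold2_end = t4)
  }
  if (any(diff(pb) < -1e-12))
    stop("phase boundaries are not increasing for '", spec$condition_id, "'")
  structure(list(times = times, levels = levels, phase_boundaries = pb,
                 band_halfwidth = spec$trace_band_halfwidth, spec = spec),
            class = "desired_trace")
}

#' Evaluate a desired trace
#'
#' Linear interpolation of the designed profile; times before onset return 0
#' and times after the trace end hold the final level.
#'
#' @param trace a [desired_trace()][build_desired_trace()].
#' @param t times in seconds from contraction onset.
#' @return Levels in %% MVT.
#' @export
trace_level <- function(trace, t) {
  stopifnot(inherits(trace, "desired_trace"))
  stats::approx(trace$times, trace$levels, xout = t, rule = 2)$y
}

#' Condition library for both experiments
#'
#' Experiment 1: one reference condition (40%% MVT) and four test conditions
#' (60 to 40%% MVT) with descending ramp durations of 0.25, 0.5, 1 and 2 s.
#' Experiment 2: three reference conditions (15/30/45%% MVT) and three test
#' conditions (85 to 15/30/45%% MVT) with both ramps at 20%% MVT/s.
#'
#' @param experiment 1 or 2.
#' @return Named list of [protocol_spec()] objects; test specs carry a
#'   `paired_reference` attribute and vice versa.
#' @export
protocol_library <- function(experiment) {
  if (experiment == 1) {
    descends <- c(`0.25-s` = 0.25, `0.5-s` = 0.5, `1-s` = 1, `2-s` = 2)
    tests <- lapply(names(descends), function(nm)
      protocol_spec(1, nm, 60, 40, descends[[nm]]))
    names(tests) <- names(descends)
    # reference hold boundaries: intersection of the four test conditions'
    # solved hold spans (all share ascend 3 s and hold2_end 13.5 s)
    h1 <- sapply(tests, function(s) {
      tr <- build_desired_trace(s); tr$phase_boundaries[["hold1_end"]] })
    h2 <- sapply(tests, function(s) {
      tr <- build_desired_trace(s); tr$phase_boundaries[["hold2_start"]] })
    ref <- protocol_spec(1, "reference", 40, 40, 0, role = "reference",
                         boundaries = list(hold1 = c(3, min(h1)),
                                           hold2 = c(max(h2), 13.5)))
    c(list(reference = ref), tests)
  } else if (experiment == 2) {
    drops <- list(`85-15` = list(h2 = 15, dur = 5),
                  `85-30` = list(h2 = 30, dur = 5.75),
                  `85-45` = list(h2 = 45, dur = 6.5))
    out <- list()
    for (nm in names(drops)) {
      d <- drops[[nm]]
      descend <- (85 - d$h2) / 20
      test <- protocol_spec(2, nm, 85, d$h2, descend, hold2_duration = d$dur)
      tr <- build_desired_trace(test)
      refnm <- as.character(d$h2)
      ref <- protocol_spec(2, refnm, d$h2, d$h2, 0, role = "reference",
                           boundaries = list(
                             hold1 = unname(tr$phase_boundaries[c("hold1_start", "hold1_end")]),
                             hold2 = unname(tr$phase_boundaries[c("hold2_start", "hold2_end")])))
      attr(test, "paired_reference") <- refnm
      attr(ref, "paired_test") <- nm
      out[[refnm]] <- ref
      out[[nm]] <- test
    }
    out
  } else stop("experiment must be 1 or 2")
}

#' Detect contraction onset
#'
#' First time the normalized active torque exceeds a threshold and stays
#' above it for a sustained period (default 1%% MVT for >= 100 ms). The
#' detector is deliberately simple; both parameters are exposed.
#'
#' @param active_torque_norm active torque [ts_channel()] in %% MVT.
#' @param threshold threshold, %% MVT (default 1).
#' @param sustain minimum supra-threshold duration, seconds (default 0.1).
#' @return Onset time in seconds (acquisition clock).
#' @export
detect_contraction_onset <- function(active_torque_norm, threshold = 1,
                                     sustain = 0.1) {
  stopifnot(inherits(active_torque_norm, "ts_channel"))
  v <- active_torque_norm$values
  k <- max(1L, round(sustain * active_torque_norm$sampling_rate))
  above <- v > threshold
  if (length(above) >= k) {
    # first index whose next k samples are all above threshold
    csum <- cumsum(c(0, as.numeric(above)))
    idx <- which(csum[seq_len(length(above) - k + 1L) + k] -
                   csum[seq_len(length(above) - k + 1L)] == k)
    if (length(idx))
      return(channel_times(active_torque_norm)[idx[1]])
  }
  stop(sprintf(
    "contraction onset not found: no crossing of %.3g %%MVT sustained for %.3g s",
    threshold, sustain))
}

#' Torque-matching error
#'
#' Maximum absolute deviation between the produced active torque and the
#' midline of the displayed band (the desired trace), from contraction onset
#' to the end of Hold 2, in %% MVT.
#'
#' @param active_torque_norm active torque [ts_channel()] in %% MVT.
#' @param trace a [desired_trace()][build_desired_trace()].
#' @param onset detected contraction onset, seconds (acquisition clock).
#' @return Matching error in %% MVT.
#' @export
torque_matching_error <- function(active_torque_norm, trace, onset) {
  stopifnot(inherits(active_torque_norm, "ts_channel"),
            inherits(trace, "desired_trace"))
  span <- onset + c(0, trace$phase_boundaries[["hold2_end"]])
  tt <- channel_times(active_torque_norm)
  if (span[1] < tt[1] - 1e-9 || span[2] > tt[length(tt)] + 1e-9)
    stop(sprintf(
      "evaluation span [%.4g, %.4g] s not covered by active torque channel",
      span[1], span[2]))
  keep <- tt >= span[1] - 1e-12 & tt <= span[2] + 1e-12
  desired <- trace_level(trace, tt[keep] - onset)
  max(abs(active_torque_norm$values[keep] - desired))
}

#' Dip threshold from pilot variability
#'
#' The validity rule for the descent between holds uses a threshold two
#' standard deviations above the pilot-study mean Hold 2 torque variability:
#' 0.6 +/- 0.1 Nm gives 0.8 Nm (Experiment 1) and 0.8 +/- 0.6 Nm gives
#' 2 Nm (Experiment 2).
#'
#' @param pilot_mean,pilot_sd pilot mean and SD of Hold 2 torque
#'   variability, Nm (both >= 0).
#' @return Threshold in Nm, `pilot_mean + 2 * pilot_sd`.
#' @export
dip_threshold_from_pilot <- function(pilot_mean, pilot_sd) {
  if (pilot_mean < 0 || pilot_sd < 0)
    stop("pilot mean and sd must be non-negative")
  pilot_mean + 2 * pilot_sd
}

#' Trial validity rules
#'
#' @param experiment 1 or 2, fixing the default dip threshold (0.8 / 2 Nm).
#' @param max_matching_error exclusion bound on the matching error, %% MVT
#'   (default 10; strict `>` comparison).
#' @param dip_threshold allowed undershoot of the descent below the Hold 2
#'   mean active torque, Nm.
#' @return An object of class `validity_rules`.
#' @export
validity_rules <- function(experiment = 1, max_matching_error = 10,
                           dip_threshold = if (experiment == 1) 0.8 else 2) {
  if (max_matching_error <= 0 || dip_threshold <= 0)
    stop("validity thresholds must be positive")
  structure(list(experiment = experiment,
                 max_matching_error = max_matching_error,
                 dip_threshold = dip_threshold),
            class = "validity_rules")
}

#' Gate a trial's validity
#'
#' A trial is valid when (a) its torque-matching error does not exceed
#' 10%% MVT (strict `>` excludes; exact equality is kept but flagged with a
#' warning) and (b) the active torque between the end of Hold 1 and the
#' start of Hold 2 never dips more than the threshold below the mean Hold 2
#' active torque.
#'
#' @param matching_error matching error in %% MVT.
#' @param active_torque_nm active torque [ts_channel()] in Nm.
#' @param trace a [desired_trace()][build_desired_trace()].
#' @param onset contraction onset, seconds (acquisition clock).
#' @param rules a [validity_rules()].
#' @return An object of class `validity_verdict`: `valid`, `matching_error`,
#'   `dip_violation`, `reasons`.
#' @export
validate_trial <- function(matching_error, active_torque_nm, trace, onset,
                           rules) {
  stopifnot(inherits(rules, "validity_rules"),
            inherits(trace, "desired_trace"))
  pb <- trace$phase_boundaries
  descent <- channel_window(active_torque_nm,
                            onset + c(pb[["hold1_end"]], pb[["hold2_start"]]),
                            min_samples = 1L)
  hold2 <- channel_window(active_torque_nm,
                          onset + c(pb[["hold2_start"]], pb[["hold2_end"]]))
  dip_violation <- min(descent) < (mean(hold2) - rules$dip_threshold)
  reasons <- character(0)
  if (matching_error > rules$max_matching_error)
    reasons <- c(reasons, "matching_error")
  else if (isTRUE(all.equal(matching_error, rules$max_matching_error)))
    warning(sprintf(
      "matching error exactly at the %g %%MVT bound; kept under the strict '>' rule",
      rules$max_matching_error))
  if (dip_violation) reasons <- c(reasons, "dip")
  structure(list(valid = length(reasons) == 0L,
                 matching_error = matching_error,
                 dip_violation = dip_violation, reasons = reasons),
            class = "validity_verdict")
}

#' Hold-phase analysis windows
#'
#' By default the solved hold spans trimmed by a 0.25-s guard at both ends,
#' keeping ramp transients, filter edge effects and onset-detection jitter
#' out of the steady-state means (the representative-figure windows are
#' similarly interior to the solved holds). Presets: `"fig2"` (4-7 s and
#' 10-13 s from onset) and `"fig4"` (5-6 s and 11-14 s).
#'
#' @param trace a [desired_trace()][build_desired_trace()].
#' @param onset contraction onset, seconds (acquisition clock).
#' @param policy `"solved"`, `"fig2"` or `"fig4"`.
#' @param guard guard at each end of each hold, seconds (default 0.25).
#' @return List with `hold1` and `hold2` windows (acquisition clock).
#' @export
hold_windows <- function(trace, onset, policy = c("solved", "fig2", "fig4"),
                         guard = 0.25) {
  policy <- match.arg(policy)
  pb <- trace$phase_boundaries
  w <- switch(policy,
    solved = list(hold1 = c(pb[["hold1_start"]] + guard,
                            pb[["hold1_end"]] - guard),
                  hold2 = c(pb[["hold2_start"]] + guard,
                            pb[["hold2_end"]] - guard)),
    fig2 = list(hold1 = c(4, 7), hold2 = c(10, 13)),
    fig4 = list(hold1 = c(5, 6), hold2 = c(11, 14)))
  lapply(w, function(x) onset + x)
}
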