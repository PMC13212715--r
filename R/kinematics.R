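#' Fascicle length trace
#'
#' Tracked (or simulated) absolute fascicle length of a representative
#' fascicle, sampled at the ultrasound frame rate (~34 samples/s). Kept on
#' its native grid throughout; window statistics never upsample it.
#'
#' @param times sample times, seconds (acquisition clock, increasing).
#' @param lengths absolute fascicle lengths, mm (> 0).
#' @param source `"tracked"` or `"simulated"`.
#' @param drift_flag whether the trace is suspected of tracking drift.
#' @return An object of class `fascicle_trace`.
#' @export
fascicle_trace <- function(times, lengths, source = "tracked",
                           drift_flag = FALSE) {
  times <- as.numeric(times); lengths <- as.numeric(lengths)
  if (length(times) != length(lengths) || length(times) < 2L)
    stop("times and lengths must match and contain >= 2 samples")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("fascicle lengths must be finite and positive")
  if (any(diff(times) <= 0)) stop("fascicle times must be increasing")
  structure(list(times = times, lengths = lengths, source = source,
                 drift_flag = isTRUE(drift_flag)),
            class = "fascicle_trace")
}

fascicle_window <- function(fascicle, window, min_samples = 2L) {
  keep <- fascicle$times >= window[1] - 1e-9 &
    fascicle$times <= window[2] + 1e-9
  if (window[1] < fascicle$times[1] - 1e-9 ||
      window[2] > fascicle$times[length(fascicle$times)] + 1e-9)
    stop(sprintf("window [%.4g, %.4g] s not covered by fascicle trace [%.4g, %.4g] s",
                 window[1], window[2], fascicle$times[1],
                 fascicle$times[length(fascicle$times)]))
  v <- fascicle$lengths[keep]
  if (length(v) < min_samples)
    stop(sprintf("fascicle window [%.4g, %.4g] s holds %d sample(s); need >= %d",
                 window[1], window[2], length(v), min_samples))
  list(t = fascicle$times[keep], l = v)
}

#' Mean of a channel over a hold window
#'
#' @param channel a [ts_channel()].
#' @param window `c(start, end)` seconds, acquisition clock.
#' @return Arithmetic mean over the closed window.
#' @export
hold_mean <- function(channel, window) {
  mean(channel_window(channel, window))
}

#' Mean fascicle length over a hold window
#' @param fascicle a [fascicle_trace()].
#' @param window `c(start, end)` seconds.
#' @return Mean length in mm.
#' @export
fascicle_hold_mean <- function(fascicle, window) {
  mean(fascicle_window(fascicle, window)$l)
}

#' Fascicle shortening amplitude
#'
#' Range (max - min) of fascicle length from 0.5 s before contraction onset
#' until the start of Hold 2, covering the force-development phase in which
#' the fascicles shorten against the stretching series-elastic tissue.
#'
#' @param fascicle a [fascicle_trace()].
#' @param onset contraction onset, seconds (acquisition clock).
#' @param hold2_start Hold 2 start, seconds (acquisition clock).
#' @return Shortening amplitude in mm (>= 0).
#' @export
shortening_amplitude <- function(fascicle, onset, hold2_start) {
  w <- fascicle_window(fascicle, c(onset - 0.5, hold2_start))
  max(w$l) - min(w$l)
}

#' Fascicle lengthening amplitude
#'
#' Peak-to-peak fascicle length change between the end of Hold 1 and the
#' start of Hold 2 (the torque-reduction phase, where tendon recoil
#' lengthens the fascicles), both in mm and as a percentage of the length
#' before lengthening (the length at the end of Hold 1).
#'
#' @param fascicle a [fascicle_trace()].
#' @param hold1_end,hold2_start phase boundaries, seconds (acquisition
#'   clock).
#' @return List with `amplitude_mm` and `amplitude_pct`.
#' @export
lengthening_amplitude <- function(fascicle, hold1_end, hold2_start) {
  w <- fascicle_window(fascicle, c(hold1_end, hold2_start))
  amp <- max(w$l) - min(w$l)
  list(amplitude_mm = amp, amplitude_pct = 100 * amp / w$l[1])
}

#' Maximum fascicle lengthening speed
#'
#' Maximum first time-derivative of fascicle length between the end of
#' Hold 1 and the start of Hold 2, lengthening positive. The length trace is
#' low-pass smoothed (dual-pass second-order Butterworth, corrected cut-off
#' `smooth_cutoff`) before central differencing, because raw frame-to-frame
#' differences at ~34 fps amplify tracking jitter.
#'
#' @param fascicle a [fascicle_trace()] on a uniform frame grid.
#' @param hold1_end,hold2_start phase boundaries, seconds.
#' @param smooth_cutoff smoothing cut-off in Hz (default 5); `NULL` disables
#'   smoothing.
#' @return Maximum lengthening speed in mm/s.
#' @export
max_lengthening_speed <- function(fascicle, hold1_end, hold2_start,
                                  smooth_cutoff = 5) {
  dt <- diff(fascicle$times)
  fs <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs)) > 0.25 / fs)
    stop("fascicle trace is not uniformly sampled; cannot differentiate")
  l <- fascicle$lengths
  if (!is.null(smooth_cutoff)) {
    ch <- ts_channel(l, fs, name = "fascicle", units = "mm",
                     t0 = fascicle$times[1])
    l <- dual_pass_butterworth(ch, filter_spec("low-pass", smooth_cutoff))$values
  }
  n <- length(l)
  dldt <- c((l[2] - l[1]) * fs,
            (l[3:n] - l[1:(n - 2)]) * fs / 2,
            (l[n] - l[n - 1]) * fs)
  keep <- fascicle$times >= hold1_end - 1e-9 &
    fascicle$times <= hold2_start + 1e-9
  if (sum(keep) < 2L)
    stop("derivative window shorter than one inter-frame interval")
  max(dldt[keep])
}

#' Torque steadiness (coefficient of variation)
#'
#' Sample standard deviation divided by the mean of active torque over the
#' Hold 2 window, in percent. Higher CV = lower steadiness.
#'
#' @param active_torque active torque [ts_channel()] (any fixed unit).
#' @param hold2_window `c(start, end)` seconds, acquisition clock.
#' @return CV in percent.
#' @export
steadiness_cv <- function(active_torque, hold2_window) {
  v <- channel_window(active_torque, hold2_window)
  m <- mean(v)
  if (m <= 0)
    stop("CV undefined: non-positive mean active torque (", signif(m, 3), ")")
  100 * stats::sd(v) / m
}

#' Assemble all per-trial scalar outcomes
#'
#' @param hold1_torque,hold2_torque hold means, %% MVT.
#' @param hold1_emg,hold2_emg hold means, %% MVC (NA if no EMG channel).
#' @param hold1_length,hold2_length hold means, mm (NA if no fascicle data).
#' @param shortening_amplitude,lengthening_amplitude_mm,lengthening_amplitude_pct,max_lengthening_speed
#'   fascicle kinematics (NA if no fascicle data).
#' @param steadiness_cv Hold 2 CV, percent.
#' @param matching_error torque-matching error, %% MVT.
#' @param verdict a `validity_verdict`.
#' @return An object of class `trial_metrics`; `as.data.frame()` turns it
#'   into a one-row table.
#' @export
trial_metrics <- function(hold1_torque, hold2_torque, hold1_emg = NA_real_,
                          hold2_emg = NA_real_, hold1_length = NA_real_,
                          hold2_length = NA_real_,
                          shortening_amplitude = NA_real_,
                          lengthening_amplitude_mm = NA_real_,
                          lengthening_amplitude_pct = NA_real_,
                          max_lengthening_speed = NA_real_,
                          steadiness_cv = NA_real_, matching_error = NA_real_,
                          verdict = NULL) {
  structure(list(hold1_torque = hold1_torque, hold2_torque = hold2_torque,
                 hold1_emg = hold1_emg, hold2_emg = hold2_emg,
                 hold1_length = hold1_length, hold2_length = hold2_length,
                 shortening_amplitude = shortening_amplitude,
                 lengthening_amplitude_mm = lengthening_amplitude_mm,
                 lengthening_amplitude_pct = lengthening_amplitude_pct,
                 max_lengthening_speed = max_lengthening_speed,
                 steadiness_cv = steadiness_cv,
                 matching_error = matching_error, verdict = verdict),
            class = "trial_metrics")
}

metric_fields <- function() {
  c("hold1_torque", "hold2_torque", "hold1_emg", "hold2_emg",
    "hold1_length", "hold2_length", "shortening_amplitude",
    "lengthening_amplitude_mm", "lengthening_amplitude_pct",
    "max_lengthening_speed", "steadiness_cv", "matching_error")
}

#' @export
as.data.frame.trial_metrics <- function(x, ...) {
  d <- as.data.frame(x[metric_fields()])
  d$valid <- if (is.null(x$verdict)) NA else x$verdict$valid
  d
}

#' Average trial metrics within a condition
#'
#' Per-field mean over the valid trials of a condition (invalid trials are
#' excluded from every field). A condition with no valid trials raises a
#' `condition_excluded` error, mirroring participant exclusion when a
#' condition has no valid trials.
#'
#' @param metrics list of [trial_metrics()] objects.
#' @param valid_only drop invalid trials first (default TRUE).
#' @return One-row data.frame of field means plus `n_valid`.
#' @export
condition_average <- function(metrics, valid_only = TRUE) {
  stopifnot(length(metrics) >= 1L)
  if (valid_only)
    metrics <- Filter(function(m) is.null(m$verdict) || m$verdict$valid,
                      metrics)
  if (length(metrics) == 0L) {
    e <- simpleError("condition excluded: zero valid trials")
    class(e) <- c("condition_excluded", class(e))
    stop(e)
  }
  rows <- do.call(rbind, lapply(metrics, function(m)
    as.data.frame(m)[metric_fields()]))
  out <- as.data.frame(lapply(rows, mean))
  out$n_valid <- length(metrics)
  out
}
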