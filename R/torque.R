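#' Baseline torque before contraction onset
#'
#' Mean of the filtered recorded torque over the window
#' `[onset_time - window, onset_time)`. Window lengths follow the protocol:
#' 1 s for all submaximal voluntary contractions, 0.5 s for MVCs in
#' Experiment 1 and 0.25 s for MVCs in Experiment 2.
#'
#' @param filtered_torque a filtered torque [ts_channel()] in Nm.
#' @param onset_time contraction onset, seconds (acquisition clock).
#' @param window pre-onset averaging window length, seconds.
#' @return Baseline torque in Nm.
#' @export
baseline_torque <- function(filtered_torque, onset_time, window = 1.0) {
  stopifnot(inherits(filtered_torque, "ts_channel"))
  if (!window %in% c(1.0, 0.5, 0.25))
    warning("non-protocol baseline window of ", window, " s")
  start <- onset_time - window
  if (start < filtered_torque$t0 - 1e-9)
    stop(sprintf(
      "insufficient pre-onset data: baseline window starts at %.4g s but channel starts at %.4g s (short by %.4g s)",
      start, filtered_torque$t0, filtered_torque$t0 - start))
  tt <- channel_times(filtered_torque)
  v <- filtered_torque$values[tt >= start - 1e-12 & tt < onset_time - 1e-12]
  if (length(v) < 2L)
    stop("baseline window contains fewer than 2 samples")
  mean(v)
}

#' Active torque
#'
#' Subtracts the baseline (resting) torque from the filtered recorded torque.
#'
#' @param filtered_torque a filtered torque [ts_channel()] in Nm.
#' @param baseline baseline torque in Nm (finite scalar).
#' @return A [ts_channel()] of active torque in Nm.
#' @export
active_torque <- function(filtered_torque, baseline) {
  stopifnot(inherits(filtered_torque, "ts_channel"),
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  channel_with(filtered_torque, filtered_torque$values - baseline,
               name = "active_torque")
}

#' Normalization context from an MVC trial
#'
#' Holds the maximum voluntary torque (MVT) and the MVC EMG envelope
#' reference. Both are means over a 0.5-s window centred on the maximum of
#' the corresponding already-filtered signal (filtered active torque;
#' smoothed envelope). If the centred window would extend beyond the trial,
#' an error is raised rather than clamping.
#'
#' @param mvc_active_torque filtered active torque [ts_channel()] of the MVC
#'   trial, Nm.
#' @param mvc_emg_envelope EMG envelope [ts_channel()] of the MVC trial.
#' @param window reference window length in seconds (default 0.5).
#' @return An object of class `normalization_context` with fields `mvt` (Nm)
#'   and `mvc_emg_amplitude` (envelope units).
#' @export
normalization_context <- function(mvc_active_torque, mvc_emg_envelope,
                                  window = 0.5) {
  mvt <- peak_window_mean(mvc_active_torque, window)
  emg <- peak_window_mean(mvc_emg_envelope, window)
  if (mvt <= 0) stop("MVT reference is non-positive: ", mvt)
  if (emg <= 0) stop("MVC EMG reference is non-positive: ", emg)
  structure(list(mvt = mvt, mvc_emg_amplitude = emg, mvc_window = window),
            class = "normalization_context")
}

# Mean over a window of `window` s centred on the signal maximum; the window
# must fit inside the trial (no clamping).
peak_window_mean <- function(channel, window = 0.5) {
  stopifnot(inherits(channel, "ts_channel"))
  tt <- channel_times(channel)
  tmax <- tt[which.max(channel$values)]
  w <- c(tmax - window / 2, tmax + window / 2)
  if (w[1] < channel$t0 - 1e-9 || w[2] > channel_end_time(channel) + 1e-9)
    stop(sprintf(
      "reference window [%.4g, %.4g] s centred on the maximum extends beyond trial bounds [%.4g, %.4g] s",
      w[1], w[2], channel$t0, channel_end_time(channel)))
  mean(channel_window(channel, w))
}

#' Normalize torque or EMG to the MVC references
#'
#' Converts absolute values to percent of the MVC reference: `% MVT` for
#' torque, `% MVC` for EMG envelopes. 100 corresponds to the 0.5-s
#' MVC-window mean.
#'
#' @param x a [ts_channel()] or numeric vector/scalar.
#' @param context a [normalization_context()].
#' @param kind `"torque"` or `"emg"`.
#' @return Same shape as `x`, in percent.
#' @export
normalize_to_mvc <- function(x, context, kind = c("torque", "emg")) {
  kind <- match.arg(kind)
  stopifnot(inherits(context, "normalization_context"))
  ref <- if (kind == "torque") context$mvt else context$mvc_emg_amplitude
  if (inherits(x, "ts_channel")) {
    channel_with(x, 100 * x$values / ref,
                 units = if (kind == "torque") "%MVT" else "%MVC")
  } else {
    100 * x / ref
  }
}
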