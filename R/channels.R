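#' Uniformly sampled time-series channel
#'
#' The basic container for every recorded or simulated signal: net joint
#' torque and crank-arm angle (2 kHz), raw surface EMG (2 kHz) and tracked
#' fascicle length (~34 samples/s). Sampling is assumed uniform; sample `i`
#' (1-based) sits at `t0 + (i - 1) / sampling_rate` seconds on the shared
#' acquisition clock.
#'
#' @param values numeric vector of samples (finite, length >= 2).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param name channel label, e.g. `"torque"`.
#' @param units unit label (`"Nm"`, `"degrees"`, `"V"`, `"mm"`, `"%MVT"`,
#'   `"%MVC"`, `"a.u."`).
#' @param t0 acquisition-clock time of the first sample, seconds.
#' @return An object of class `ts_channel`.
#' @export
ts_channel <- function(values, sampling_rate, name = "signal", units = "a.u.",
                       t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("ts_channel '", name, "': need at least 2 samples, got ",
         length(values))
  if (!all(is.finite(values)))
    stop("ts_channel '", name, "': values must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("ts_channel '", name, "': sampling_rate must be a positive scalar")
  structure(
    list(values = values, sampling_rate = as.numeric(sampling_rate),
         name = as.character(name), units = as.character(units),
         t0 = as.numeric(t0)),
    class = "ts_channel"
  )
}

#' @export
print.ts_channel <- function(x, ...) {
  cat(sprintf("<ts_channel '%s'> %d samples @ %g Hz, t = [%.4g, %.4g] s, units: %s\n",
              x$name, length(x$values), x$sampling_rate, x$t0,
              channel_end_time(x), x$units))
  invisible(x)
}

#' Sample times of a channel
#' @param channel a [ts_channel()].
#' @return numeric vector of times in seconds.
#' @export
channel_times <- function(channel) {
  channel$t0 + (seq_along(channel$values) - 1L) / channel$sampling_rate
}

channel_end_time <- function(channel) {
  channel$t0 + (length(channel$values) - 1L) / channel$sampling_rate
}

#' Extract the samples of a channel falling inside a closed time window
#'
#' @param channel a [ts_channel()].
#' @param window numeric length-2, `c(start, end)` in seconds (closed window).
#' @param min_samples minimum number of samples required inside the window.
#' @return numeric vector of samples.
#' @export
channel_window <- function(channel, window, min_samples = 2L) {
  stopifnot(length(window) == 2L)
  if (!all(is.finite(window)) || window[2] <= window[1])
    stop("invalid window [", window[1], ", ", window[2], "]")
  if (window[1] < channel$t0 - 0.5 / channel$sampling_rate ||
      window[2] > channel_end_time(channel) + 0.5 / channel$sampling_rate)
    stop(sprintf(
      "window [%.4g, %.4g] s not covered by channel '%s' spanning [%.4g, %.4g] s",
      window[1], window[2], channel$name, channel$t0, channel_end_time(channel)))
  tt <- channel_times(channel)
  keep <- tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12
  v <- channel$values[keep]
  if (length(v) < min_samples)
    stop(sprintf("window [%.4g, %.4g] s on channel '%s' contains %d sample(s); need >= %d",
                 window[1], window[2], channel$name, length(v), min_samples))
  v
}

# Replace the values of a channel, keeping its clock and metadata.
channel_with <- function(channel, values, name = channel$name,
                         units = channel$units) {
  ts_channel(values, channel$sampling_rate, name = name, units = units,
             t0 = channel$t0)
}
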