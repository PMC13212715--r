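#' Multi-pass Butterworth cut-off correction
#'
#' A Butterworth low-pass filter applied `passes` times (e.g. once forward and
#' once backward for zero phase) attenuates more than -3 dB at its design
#' cut-off. To place the -3 dB point of the cascade at the desired frequency,
#' each pass is designed at `f_design = f_desired / C` with
#' `C = (2^(1/passes) - 1)^(1 / (2 * order_per_pass))`.
#'
#' For a single pass `C = 1` and no correction is applied. For the usual
#' dual-pass second-order filter, `C ~= 0.8022`, i.e. a desired 20 Hz cut-off
#' is designed at ~24.94 Hz.
#'
#' @param desired_cutoff desired -3 dB frequency of the cascade, Hz (> 0).
#' @param order_per_pass Butterworth order of each pass (>= 1).
#' @param passes number of passes (>= 1; 2 = dual-pass forward-backward).
#' @return The corrected (design) cut-off frequency in Hz.
#' @export
corrected_cutoff <- function(desired_cutoff, order_per_pass = 2L, passes = 2L) {
  if (!is.numeric(desired_cutoff) || any(desired_cutoff <= 0))
    stop("desired_cutoff must be > 0")
  if (order_per_pass < 1L) stop("order_per_pass must be >= 1")
  if (passes < 1L) stop("passes must be >= 1")
  C <- (2^(1 / passes) - 1)^(1 / (2 * order_per_pass))
  desired_cutoff / C
}

#' Filter specification
#'
#' Describes a low-pass or band-pass Butterworth filter the way it appears in
#' a run configuration: by its *desired* cut-off(s); the multi-pass correction
#' is applied internally at design time.
#'
#' @param kind `"low-pass"` or `"band-pass"`.
#' @param desired_cutoffs one (low-pass) or two increasing (band-pass)
#'   cut-off frequencies in Hz.
#' @param order_per_pass Butterworth order per pass (default 2).
#' @param passes number of passes (default 2 = dual-pass zero-phase).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low-pass", "band-pass"), desired_cutoffs,
                        order_per_pass = 2L, passes = 2L) {
  kind <- match.arg(kind)
  desired_cutoffs <- as.numeric(desired_cutoffs)
  if (any(!is.finite(desired_cutoffs)) || any(desired_cutoffs <= 0))
    stop("desired_cutoffs must be finite and > 0")
  if (kind == "low-pass" && length(desired_cutoffs) != 1L)
    stop("low-pass filter_spec takes exactly one cutoff")
  if (kind == "band-pass") {
    if (length(desired_cutoffs) != 2L)
      stop("band-pass filter_spec takes exactly two cutoffs")
    if (desired_cutoffs[1] >= desired_cutoffs[2])
      stop("band-pass cutoffs must satisfy low < high")
  }
  if (order_per_pass < 1L || passes < 1L)
    stop("order_per_pass and passes must be >= 1")
  structure(list(kind = kind, desired_cutoffs = desired_cutoffs,
                 order_per_pass = as.integer(order_per_pass),
                 passes = as.integer(passes)),
            class = "filter_spec")
}

# Digital Butterworth design (bilinear transform of the analog prototype).
# Returns list(b, a) for H(z) = B(z)/A(z) with a[1] == 1.
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop(sprintf(
      "invalid filter: design cutoff %.4g Hz must lie in (0, Nyquist = %.4g Hz)",
      cutoff_hz, fs / 2))
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff, rad/s
  if (type == "low") {
    p <- warped * p_proto
    z_an <- complex(0)                         # zeros at analog infinity
  } else {
    p <- warped / p_proto
    z_an <- rep(0 + 0i, order)                 # zeros at s = 0
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  pz <- (2 * fs + p) / (2 * fs - p)
  zz <- if (length(z_an)) (2 * fs + z_an) / (2 * fs - z_an) else complex(0)
  zz <- c(zz, rep(-1 + 0i, order - length(zz)))  # zeros from analog infinity
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  # unit gain at DC (low-pass) or Nyquist (high-pass)
  zref <- if (type == "low") 1 else -1
  gain <- sum(b * zref^(seq_along(b) - 1)) / sum(a * zref^(seq_along(a) - 1))
  list(b = b / gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

# Single forward pass of an IIR filter, zero initial conditions.
iir_filter <- function(x, b, a) {
  nb <- length(b)
  u <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  u <- as.numeric(u)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L)
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  u
}

# Forward-backward (zero-phase) application with odd-reflection padding.
# The mean is removed before filtering and restored through the filter's DC
# gain, so constants pass through exactly; padding length covers the slower
# of the spec minimum (3 * order * passes, 1% of the signal) and the filter's
# own settling time (from the largest pole radius).
filtfilt_reflect <- function(x, b, a, order) {
  n <- length(x)
  rmax <- max(Mod(polyroot(rev(a))))
  settle <- if (rmax < 1) ceiling(log(1e-10) / log(rmax)) else n
  padlen <- max(3L * as.integer(order) * 2L, ceiling(0.01 * n), settle)
  if (n <= padlen + 1L)
    stop(sprintf(
      "signal too short for stable forward-backward filtering: %d samples, need > %d",
      n, padlen + 1L))
  dc <- mean(x)
  dcgain <- sum(b) / sum(a)
  x <- x - dc
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- c(pre, x, post)
  y <- iir_filter(y, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(padlen + 1L):(padlen + n)] + dc * dcgain^2
}

# Resolve a filter_spec into the list of (b, a) sections it cascades,
# with the multi-pass cutoff correction applied per edge.
filter_sections <- function(spec, fs) {
  C <- (2^(1 / spec$passes) - 1)^(1 / (2 * spec$order_per_pass))
  if (spec$kind == "low-pass") {
    list(butter_design(spec$order_per_pass, spec$desired_cutoffs / C, fs,
                       "low"))
  } else {
    # high-pass edge: the design cutoff moves *down* (f * C) so the cascaded
    # -3 dB point lands on the desired edge; low-pass edge moves up (f / C).
    list(butter_design(spec$order_per_pass, spec$desired_cutoffs[1] * C, fs,
                       "high"),
         butter_design(spec$order_per_pass, spec$desired_cutoffs[2] / C, fs,
                       "low"))
  }
}

#' Zero-phase (dual-pass) Butterworth filtering
#'
#' Applies the filter described by `spec` to a channel. With `passes = 2`
#' (the default) the filter runs once forward and once backward, giving zero
#' phase lag and squared magnitude response; the design cut-offs are corrected
#' (see [corrected_cutoff()]) so that the composite -3 dB point sits at the
#' desired frequency. Edge transients are suppressed by odd-reflection
#' padding of length `max(12, 1%% of the signal)`.
#'
#' @param channel a [ts_channel()].
#' @param spec a [filter_spec()].
#' @return A filtered [ts_channel()] of identical length and clock.
#' @export
dual_pass_butterworth <- function(channel, spec) {
  stopifnot(inherits(channel, "ts_channel"), inherits(spec, "filter_spec"))
  sections <- filter_sections(spec, channel$sampling_rate)
  x <- channel$values
  for (s in sections) {
    x <- if (spec$passes == 1L) {
      iir_filter(x, s$b, s$a)
    } else {
      filtfilt_reflect(x, s$b, s$a, spec$order_per_pass)
    }
  }
  channel_with(channel, x)
}

#' EMG linear envelope
#'
#' Four fixed stages, in order: (1) dual-pass second-order band-pass
#' 20-400 Hz (cut-off corrected); (2) subtraction of the whole-trial mean of
#' the band-passed signal; (3) full-wave rectification; (4) dual-pass
#' second-order low-pass smoothing at a corrected 10 Hz cut-off. The
#' zero-phase low-pass of a rectified signal may undershoot below zero at
#' sharp transitions; no sample-wise non-negativity is imposed.
#'
#' @param raw_emg a [ts_channel()] with sampling rate above `2 * band[2]`.
#' @param band band-pass edges in Hz (default `c(20, 400)`).
#' @param smooth_cutoff smoothing low-pass desired cut-off in Hz (default 10).
#' @param order_per_pass Butterworth order per pass for all stages (default 2).
#' @return The envelope as a [ts_channel()].
#' @export
emg_envelope <- function(raw_emg, band = c(20, 400), smooth_cutoff = 10,
                         order_per_pass = 2L) {
  stopifnot(inherits(raw_emg, "ts_channel"))
  if (raw_emg$sampling_rate <= 2 * band[2])
    stop(sprintf(
      "EMG sampling rate %.4g Hz too low for band edge %.4g Hz (need > %.4g Hz)",
      raw_emg$sampling_rate, band[2], 2 * band[2]))
  bp <- dual_pass_butterworth(
    raw_emg, filter_spec("band-pass", band, order_per_pass, passes = 2L))
  centred <- bp$values - mean(bp$values)
  rectified <- abs(centred)
  sm <- dual_pass_butterworth(
    channel_with(raw_emg, rectified),
    filter_spec("low-pass", smooth_cutoff, order_per_pass, passes = 2L))
  channel_with(sm, sm$values, name = paste0(raw_emg$name, "_envelope"))
}
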