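#' Muscle-tendon-unit parameters for the simulator
#'
#' Two-element Hill-type model of the dorsiflexor group acting through a
#' fixed effective moment arm, so forces are expressed directly in Nm. A
#' contractile element (CE, the fascicles) with Gaussian force-length and
#' hyperbolic force-velocity properties is in series with an elastic element
#' (SEE, tendon + aponeurosis) with a quadratic (toe-dominated) force-
#' extension curve. The MTU length is constant (fixed-end contraction), so
#' any SEE stretch shortens the fascicles and any SEE recoil lengthens them;
#' pennation is absorbed into the length constant.
#'
#' Defaults place the model near the printed group anchors: maximal
#' voluntary torque ~40 Nm, fascicle length ~83 mm at 40%% MVT, and
#' lengthening amplitudes of ~3.5-7 mm for the 85-to-15/30/45%% MVT drops.
#'
#' @param f_max maximal isometric CE force in Nm-equivalent (default 44).
#' @param l_opt optimal fascicle length, mm (default 82).
#' @param fl_width Gaussian force-length width, fraction of `l_opt`
#'   (default 0.5; the operating region sits near the plateau).
#' @param fv_curvature Hill force-velocity curvature a/F0 (default 0.25).
#' @param v_max_rel maximal shortening velocity in optimal lengths per
#'   second (default 8).
#' @param see_rest_length SEE rest length, mm (default 260).
#' @param see_strain_at_fmax SEE strain at `f_max` (default 0.05, i.e.
#'   13 mm of stretch at maximal force).
#' @param see_linear_frac weight of the linear term in the SEE
#'   force-extension curve (default 0.15; the remainder is the quadratic
#'   toe term).
#' @param activation_tau_up,activation_tau_down activation/deactivation time
#'   constants, s (defaults 0.015 / 0.05).
#' @param mtu_constant_length fixed MTU length, mm (default 351, giving a
#'   passive fascicle length of 91 mm).
#' @return An object of class `mtu_params`.
#' @export
mtu_params <- function(f_max = 44, l_opt = 82, fl_width = 0.5,
                       fv_curvature = 0.25, v_max_rel = 8,
                       see_rest_length = 260, see_strain_at_fmax = 0.05,
                       see_linear_frac = 0.15,
                       activation_tau_up = 0.015, activation_tau_down = 0.05,
                       mtu_constant_length = 351) {
  p <- list(f_max = f_max, l_opt = l_opt, fl_width = fl_width,
            fv_curvature = fv_curvature, v_max_rel = v_max_rel,
            see_rest_length = see_rest_length,
            see_strain_at_fmax = see_strain_at_fmax,
            see_linear_frac = see_linear_frac,
            activation_tau_up = activation_tau_up,
            activation_tau_down = activation_tau_down,
            mtu_constant_length = mtu_constant_length)
  if (any(unlist(p) <= 0)) stop("all mtu_params must be positive")
  if (!(see_strain_at_fmax > 0 && see_strain_at_fmax < 0.1))
    stop("see_strain_at_fmax must lie in (0, 0.1)")
  if (see_linear_frac >= 1) stop("see_linear_frac must lie in (0, 1)")
  p$d_max <- see_rest_length * see_strain_at_fmax
  p$l_f_rest <- mtu_constant_length - see_rest_length
  if (p$l_f_rest <= l_opt * 0.5 || l_opt >= mtu_constant_length)
    stop("inconsistent lengths: need l_opt < mtu_constant_length and a positive passive fascicle length")
  structure(p, class = "mtu_params")
}

fl_gauss <- function(l, p) exp(-((l - p$l_opt) / (p$fl_width * p$l_opt))^2)

# SEE force (Nm-equivalent) from stretch d (mm): quadratic toe stiffening
# into a linear region, F = f_max * (c2 * (d/d_max)^2 + c1 * (d/d_max)) with
# c1 + c2 = 1, so F(d_max) = f_max and stiffness is positive at zero force.
see_force <- function(d, p) {
  x <- pmax(d, 0) / p$d_max
  c1 <- p$see_linear_frac
  p$f_max * ((1 - c1) * x^2 + c1 * x)
}
see_stretch <- function(force, p) {
  f <- pmax(force, 0) / p$f_max
  c1 <- p$see_linear_frac; c2 <- 1 - c1
  p$d_max * (-c1 + sqrt(c1^2 + 4 * c2 * f)) / (2 * c2)
}

#' Quasi-static maximal voluntary torque of a parameter set
#'
#' Fixed-point solution of the force balance at full activation and zero
#' fascicle velocity: `T = f_max * fl(l_f_rest - d(T))`.
#'
#' @param p an [mtu_params()].
#' @return MVT in Nm.
#' @export
mvc_torque <- function(p) {
  T <- 0.9 * p$f_max
  for (i in 1:100) T <- p$f_max * fl_gauss(p$l_f_rest - see_stretch(T, p), p)
  T
}

#' Simulation configuration
#'
#' @param experiment 1 or 2 (selects the [protocol_library()]).
#' @param rate_hz torque/EMG sampling and integration rate, Hz
#'   (default 2000; tests use reduced rates).
#' @param fascicle_rate_hz ultrasound frame rate, Hz (default 34).
#' @param channels which channels to synthesize, subset of
#'   `c("torque", "emg", "fascicle")`.
#' @param torque_noise_cv signal-dependent torque noise, %% of instantaneous
#'   torque (default 1.5, matching hold-phase CVs of ~1-4%%).
#' @param steadiness_effect named vector of extra Hold 2 CV (%%) per
#'   condition; defaults reproduce the reported condition differences
#'   (+0.3%% for the 0.25-s drop in Experiment 1; +1.5 and +0.7%% for the
#'   85-15 and 85-30 drops in Experiment 2).
#' @param emg_noise_cv multiplicative EMG amplitude noise, %% (default 8).
#' @param emg_baseline_noise EMG noise floor, fraction of the MVC envelope
#'   (default 0.02).
#' @param tracking_drift_rate fascicle-tracking drift, mm/s from contraction
#'   onset (default 0; Fig.-4-style drift is opt-in).
#' @param tracking_noise_sd fascicle tracking jitter SD, mm (default 0.1).
#' @param sensor_noise_sd torque sensor noise floor SD, Nm (default 0.02).
#' @param baseline_torque_nm passive baseline torque offset, Nm (default 2).
#' @param pre_quiet quiescent recording before contraction onset, s
#'   (default 1.5).
#' @param post_release recording after the trace ends, s (default 1).
#' @param mtu an [mtu_params()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(experiment = 1, rate_hz = 2000, fascicle_rate_hz = 34,
                       channels = c("torque", "emg", "fascicle"),
                       torque_noise_cv = 1.5,
                       steadiness_effect = NULL,
                       emg_noise_cv = 8, emg_baseline_noise = 0.02,
                       tracking_drift_rate = 0, tracking_noise_sd = 0.1,
                       sensor_noise_sd = 0.02, baseline_torque_nm = 2,
                       pre_quiet = 1.5, post_release = 1,
                       mtu = mtu_params()) {
  if (is.null(steadiness_effect))
    steadiness_effect <- if (experiment == 1) c(`0.25-s` = 0.3)
                         else c(`85-15` = 1.5, `85-30` = 0.7)
  if (any(c(torque_noise_cv, emg_noise_cv, emg_baseline_noise,
            tracking_noise_sd, sensor_noise_sd) < 0) ||
      any(steadiness_effect < 0))
    stop("noise parameters must be >= 0")
  if ("emg" %in% channels && rate_hz <= 800)
    stop("EMG synthesis needs rate_hz > 800 (band edge 400 Hz)")
  structure(list(experiment = experiment, rate_hz = rate_hz,
                 fascicle_rate_hz = fascicle_rate_hz, channels = channels,
                 torque_noise_cv = torque_noise_cv,
                 steadiness_effect = steadiness_effect,
                 emg_noise_cv = emg_noise_cv,
                 emg_baseline_noise = emg_baseline_noise,
                 tracking_drift_rate = tracking_drift_rate,
                 tracking_noise_sd = tracking_noise_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 baseline_torque_nm = baseline_torque_nm,
                 pre_quiet = pre_quiet, post_release = post_release,
                 mtu = mtu),
            class = "sim_config")
}

# unit-variance low-frequency noise: white noise low-passed at `cutoff` Hz
lf_noise <- function(n, fs, cutoff = 10) {
  w <- stats::rnorm(n + 200)
  ch <- ts_channel(w, fs, name = "noise")
  v <- dual_pass_butterworth(ch, filter_spec("low-pass",
                                             min(cutoff, fs / 2.5)))$values
  v <- v[101:(100 + n)]
  v / stats::sd(v)
}

# closed-loop simulation core: track `desired_nm` (Nm, length n, at fs Hz)
# with a PI-plus-feedforward controller driving first-order activation.
# Returns activation, fascicle length and clean torque traces.
mtu_tracking_sim <- function(desired_nm, fs, p, mvt_nominal,
                             kp = 4, ki = 40, lead = 0.03,
                             open_loop_u = NULL) {
  n <- length(desired_nm)
  dt <- 1 / fs
  nlead <- round(lead * fs)
  des_lead <- c(desired_nm[(1 + nlead):n], rep(desired_nm[n], nlead))
  a <- 0; lf <- p$l_f_rest; ie <- 0
  s0 <- p$v_max_rel * p$l_opt / (1 + 1 / p$fv_curvature)
  vmax <- p$v_max_rel * p$l_opt
  a_vec <- lf_vec <- T_vec <- numeric(n)
  bad <- 0L; bad_max <- round(0.5 * fs)
  w2 <- (p$fl_width * p$l_opt)^2
  c1 <- p$see_linear_frac; c2 <- 1 - c1
  for (i in seq_len(n)) {
    d <- p$l_f_rest - lf
    Fsee <- if (d > 0) {
      xd <- d / p$d_max
      p$f_max * (c2 * xd * xd + c1 * xd)
    } else 0
    fl <- exp(-(lf - p$l_opt)^2 / w2)
    # controller
    if (is.null(open_loop_u)) {
      e <- (desired_nm[i] - Fsee) / mvt_nominal
      ie <- ie + dt * e
      if (ie > 0.3) ie <- 0.3 else if (ie < -0.3) ie <- -0.3
      u <- des_lead[i] / (p$f_max * fl) + kp * e + ki * ie
      if (u < 0) u <- 0 else if (u > 1) u <- 1
      if (desired_nm[i] > 0.05 * mvt_nominal && abs(e) > 0.2) {
        bad <- bad + 1L
        if (bad > bad_max)
          stop("simulation failure: tracking error > 20% MVT sustained for 0.5 s")
      } else bad <- 0L
    } else u <- open_loop_u[i]
    tau <- if (u >= a) p$activation_tau_up else p$activation_tau_down
    a <- a + dt * (u - a) / tau
    # force balance: relax the SEE stretch toward its equilibrium at the
    # current activation, rate-limited by the Hill force-velocity curve
    # (shortening positive). This semi-implicit step cannot overshoot the
    # equilibrium within a step, which keeps the stiff low-force region
    # stable at analysis sampling rates.
    cap <- max(a * fl * p$f_max, 1e-6)
    ft <- Fsee / cap
    fcap <- cap / p$f_max
    d_star <- p$d_max * (-c1 + sqrt(c1 * c1 + 4 * c2 * fcap)) / (2 * c2)
    dd <- d_star - d
    if (dd > 0) {                              # CE shortens, SEE stretches
      vcap <- vmax * (1 - ft) / (1 + ft / p$fv_curvature)
      if (dd > dt * vcap) dd <- dt * vcap
    } else {                                   # CE lengthens, SEE recoils
      vcap <- s0 * (ft - 1) / (1 + (ft - 1) / 0.5)
      if (dd < -dt * vcap) dd <- -dt * vcap
    }
    lf <- lf - dd
    if (lf > p$l_f_rest) lf <- p$l_f_rest
    if (lf < 0.4 * p$l_opt) lf <- 0.4 * p$l_opt
    a_vec[i] <- a; lf_vec[i] <- lf; T_vec[i] <- Fsee
  }
  list(activation = a_vec, fascicle = lf_vec, torque = T_vec)
}

#' Simulate one contraction trial
#'
#' Closed-loop simulation of one condition: a PI-plus-feedforward controller
#' drives commanded activation so the model torque follows the designed
#' trace; activation follows first-order dynamics; the force balance between
#' the Hill-type contractile element and the quadratic series-elastic
#' element yields the fascicle trajectory (shortening during force
#' development, lengthening by tendon recoil during the torque reduction).
#' Signal-dependent low-frequency noise is added to the recorded torque
#' (observation noise, not fed back), a raw amplitude-modulated interference
#' signal is synthesized for EMG, and the fascicle channel is subsampled to
#' the frame rate with optional drift and jitter.
#'
#' @param config a [sim_config()].
#' @param condition condition label from [protocol_library()], or `"MVC"`.
#' @param seed optional integer seed for exact reproducibility.
#' @param mtu override the configuration's [mtu_params()] (used for
#'   per-subject jitter).
#' @return An object of class `sim_trial`: `channels` (list of
#'   [ts_channel()] / [fascicle_trace()]), `ground_truth`, `condition`,
#'   `experiment`.
#' @export
simulate_trial <- function(config, condition, seed = NULL, mtu = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (condition == "MVC") return(generate_mvc_trial(config, seed = NULL,
                                                    mtu = mtu))
  p <- if (is.null(mtu)) config$mtu else mtu
  lib <- protocol_library(config$experiment)
  if (!condition %in% names(lib))
    stop("unknown condition '", condition, "' for experiment ",
         config$experiment)
  trace <- build_desired_trace(lib[[condition]])
  mvt <- mvc_torque(p)
  fs <- config$rate_hz
  onset <- config$pre_quiet
  dur <- onset + trace$spec$total_duration + config$post_release
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  frac <- trace_level(trace, tt - onset) / 100
  frac[tt < onset] <- 0
  # terminal release: ramp the command to zero after the trace ends
  tend <- onset + trace$spec$total_duration
  after <- tt >= tend
  frac[after] <- pmax(0, trace$spec$hold2_level / 100 - 0.4 * (tt[after] - tend))
  desired_nm <- frac * mvt

  sim <- mtu_tracking_sim(desired_nm, fs, p, mvt)
  pb <- trace$phase_boundaries

  # --- recorded torque: clean + baseline + signal-dependent noise ---
  cv <- rep(config$torque_noise_cv, length(tt))
  extra <- config$steadiness_effect
  truth_cv <- config$torque_noise_cv
  if (condition %in% names(extra)) {
    h2 <- onset + c(pb[["hold2_start"]], pb[["hold2_end"]])
    cv[tt >= h2[1] & tt <= h2[2]] <- config$torque_noise_cv + extra[[condition]]
    truth_cv <- config$torque_noise_cv + extra[[condition]]
  }
  noise <- lf_noise(length(tt), fs) * (cv / 100 * pmax(sim$torque, 0) +
                                         config$sensor_noise_sd)
  channels <- list(
    torque = ts_channel(sim$torque + config$baseline_torque_nm + noise, fs,
                        name = "torque", units = "Nm"))

  # --- raw EMG: amplitude-modulated band-limited interference ---
  if ("emg" %in% config$channels) {
    carrier <- stats::rnorm(length(tt))
    carrier <- dual_pass_butterworth(
      ts_channel(carrier, fs, "carrier"),
      filter_spec("band-pass", c(20, 400)))$values
    carrier <- carrier / stats::sd(carrier)
    mod <- sim$activation *
      (1 + lf_noise(length(tt), fs, 5) * config$emg_noise_cv / 100) +
      config$emg_baseline_noise
    emg_scale <- 5e-4  # volts at full activation
    raw <- emg_scale * mod * carrier / sqrt(2 / pi)
    channels$emg <- ts_channel(raw, fs, name = "emg", units = "V")
  }

  # --- fascicle channel at the ultrasound frame rate ---
  ft_times <- seq(0, dur - 1 / fs, by = 1 / config$fascicle_rate_hz)
  lf_frames <- stats::approx(tt, sim$fascicle, xout = ft_times)$y
  truth_fascicle <- fascicle_trace(ft_times, lf_frames, source = "simulated")
  if ("fascicle" %in% config$channels) {
    drift <- config$tracking_drift_rate * pmax(ft_times - onset, 0)
    jitter <- stats::rnorm(length(ft_times), 0, config$tracking_noise_sd)
    channels$fascicle <- fascicle_trace(
      ft_times, lf_frames + drift + jitter, source = "simulated",
      drift_flag = config$tracking_drift_rate != 0)
  }

  lf_win <- function(w) {
    keep <- tt >= w[1] & tt <= w[2]
    range(sim$fascicle[keep])
  }
  sa <- diff(lf_win(onset + c(-0.5, pb[["hold2_start"]])))
  la <- diff(lf_win(onset + c(pb[["hold1_end"]], pb[["hold2_start"]])))

  structure(list(
    channels = channels,
    condition = condition, experiment = config$experiment,
    ground_truth = list(
      onset = onset, mvt = mvt, trace = trace,
      activation = ts_channel(sim$activation, fs, "activation", "a.u."),
      torque_clean = ts_channel(sim$torque, fs, "torque_clean", "Nm"),
      fascicle_true = truth_fascicle,
      hold1_level = trace$spec$hold1_level,
      hold2_level = trace$spec$hold2_level,
      cv = truth_cv,
      shortening_amplitude = sa, lengthening_amplitude = la,
      baseline_torque = config$baseline_torque_nm)),
    class = "sim_trial")
}

#' Simulate a maximal voluntary contraction trial
#'
#' Open-loop drive to full activation: 0.5-s ramp up, 3-s plateau at
#' `u = 1`, 1-s release. Supplies the MVT and 100%%-MVC EMG references for
#' normalization.
#'
#' @inheritParams simulate_trial
#' @return A `sim_trial`.
#' @export
generate_mvc_trial <- function(config, seed = NULL, mtu = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(mtu)) config$mtu else mtu
  fs <- config$rate_hz
  onset <- config$pre_quiet
  dur <- onset + 0.5 + 3 + 1 + config$post_release
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  u <- pmin(pmax((tt - onset) / 0.5, 0), 1)
  # effort peaks mid-plateau (1% tent), as in real MVCs; a perfectly flat
  # plateau would put the filtered-signal maximum on the release corner
  u <- pmin(u, pmax(1 - 0.01 * abs(tt - (onset + 2)) / 1.5, 0))
  rel <- tt > onset + 3.5
  u[rel] <- pmin(u[rel], pmax(0, 1 - (tt[rel] - (onset + 3.5))))
  sim <- mtu_tracking_sim(u * 0, fs, p, 1, open_loop_u = u)
  noise <- lf_noise(length(tt), fs) *
    (config$torque_noise_cv / 100 * pmax(sim$torque, 0) +
       config$sensor_noise_sd)
  channels <- list(
    torque = ts_channel(sim$torque + config$baseline_torque_nm + noise, fs,
                        name = "torque", units = "Nm"))
  if ("emg" %in% config$channels) {
    carrier <- stats::rnorm(length(tt))
    carrier <- dual_pass_butterworth(
      ts_channel(carrier, fs, "carrier"),
      filter_spec("band-pass", c(20, 400)))$values
    carrier <- carrier / stats::sd(carrier)
    mod <- sim$activation *
      (1 + lf_noise(length(tt), fs, 5) * config$emg_noise_cv / 100) +
      config$emg_baseline_noise
    channels$emg <- ts_channel(5e-4 * mod * carrier / sqrt(2 / pi), fs,
                               name = "emg", units = "V")
  }
  ft_times <- seq(0, dur - 1 / fs, by = 1 / config$fascicle_rate_hz)
  lf_frames <- stats::approx(tt, sim$fascicle, xout = ft_times)$y
  if ("fascicle" %in% config$channels)
    channels$fascicle <- fascicle_trace(
      ft_times, lf_frames + stats::rnorm(length(ft_times), 0,
                                         config$tracking_noise_sd),
      source = "simulated")
  structure(list(
    channels = channels, condition = "MVC", experiment = config$experiment,
    ground_truth = list(
      onset = onset, mvt = mvc_torque(p),
      activation = ts_channel(sim$activation, fs, "activation", "a.u."),
      torque_clean = ts_channel(sim$torque, fs, "torque_clean", "Nm"),
      fascicle_true = fascicle_trace(ft_times, lf_frames,
                                     source = "simulated"),
      baseline_torque = config$baseline_torque_nm)),
    class = "sim_trial")
}

#' Generate a multi-subject synthetic dataset
#'
#' Per-subject MTU parameters are jittered log-normally around the
#' configuration defaults, condition order is randomized within blocks
#' (mirroring the experimental block randomization), and each subject gets
#' one MVC trial plus `trials_per_condition` submaximal trials per
#' condition. With `out_dir` the dataset is written to disk
#' (see [write_trial()]); otherwise it is returned in memory.
#'
#' @param config a [sim_config()].
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_condition trials per condition (default 1).
#' @param subject_cv named list of log-normal coefficients of variation for
#'   jittered parameters (default `f_max` 20%%, `l_opt` 8%%,
#'   `see_strain_at_fmax` 15%%).
#' @param conditions condition labels (default: the whole
#'   [protocol_library()] of the experiment).
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return Invisibly, a list with one element per subject: `id`, `mtu`,
#'   `mvc` (a `sim_trial`), `trials` (list of `sim_trial`s in block order);
#'   when `out_dir` is given, the same structure is written to disk and the
#'   manifest path is attached as attribute `manifest`.
#' @export
generate_dataset <- function(config, n_subjects, trials_per_condition = 1,
                             subject_cv = list(f_max = 0.2, l_opt = 0.08,
                                               see_strain_at_fmax = 0.15),
                             conditions = NULL, seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), n_subjects >= 2)
  set.seed(seed)
  if (is.null(conditions))
    conditions <- names(protocol_library(config$experiment))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    base <- config$mtu
    jit <- base
    for (nm in names(subject_cv)) {
      cv <- subject_cv[[nm]]
      jit[[nm]] <- base[[nm]] * exp(stats::rnorm(1, -cv^2 / 2, cv))
    }
    jit$see_strain_at_fmax <- min(jit$see_strain_at_fmax, 0.099)
    mtu <- mtu_params(f_max = jit$f_max, l_opt = jit$l_opt,
                      fl_width = jit$fl_width,
                      fv_curvature = jit$fv_curvature,
                      v_max_rel = jit$v_max_rel,
                      see_rest_length = jit$see_rest_length,
                      see_strain_at_fmax = jit$see_strain_at_fmax,
                      see_linear_frac = jit$see_linear_frac,
                      activation_tau_up = jit$activation_tau_up,
                      activation_tau_down = jit$activation_tau_down,
                      mtu_constant_length = jit$mtu_constant_length)
    mvc <- generate_mvc_trial(config, mtu = mtu)
    trials <- list()
    for (b in seq_len(trials_per_condition)) {
      for (cond in sample(conditions))  # randomized block order
        trials[[length(trials) + 1L]] <- simulate_trial(config, cond,
                                                        mtu = mtu)
    }
    subjects[[s]] <- list(id = sprintf("S%02d", s), mtu = mtu, mvc = mvc,
                          trials = trials)
  }
  out <- structure(subjects, experiment = config$experiment, seed = seed,
                   class = "sim_dataset")
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  invisible(out)
}
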