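# Shared fixtures: reduced-rate simulator configurations keep the suite
# inside a 1-CPU budget; noise levels and protocol parameters are the
# package defaults, only sampling rates and channel subsets are reduced.

quiet_cfg <- function(experiment = 1, rate_hz = 250, ...) {
  sim_config(experiment = experiment, rate_hz = rate_hz,
             channels = "torque", torque_noise_cv = 0, sensor_noise_sd = 0,
             tracking_noise_sd = 0, steadiness_effect = c(), ...)
}

noisy_cfg <- function(experiment = 1, rate_hz = 250, ...) {
  sim_config(experiment = experiment, rate_hz = rate_hz,
             channels = "torque", ...)
}

# context + trial metrics for a single simulated trial
process_one <- function(cfg, condition, rcfg = run_config(cfg$experiment)) {
  ctx <- process_mvc(generate_mvc_trial(cfg), rcfg)
  tr <- simulate_trial(cfg, condition)
  list(metrics = process_trial(tr, ctx, rcfg), trial = tr, ctx = ctx)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
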