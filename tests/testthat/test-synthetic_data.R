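# The muscle-tendon-unit generator: determinism, mechanism, calibration.

test_that("same seed gives a bit-identical trial; different seeds differ", {
  cfg <- noisy_cfg(2, rate_hz = 250)
  t1 <- simulate_trial(cfg, "85-15", seed = 7)
  t2 <- simulate_trial(cfg, "85-15", seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_trial(cfg, "85-15", seed = 8)
  expect_false(identical(t1$channels$torque$values,
                         t3$channels$torque$values))
})

test_that("quiescent phase is truly quiescent", {
  cfg <- quiet_cfg(1)
  tr <- simulate_trial(cfg, "reference", seed = 1)
  tt <- channel_times(tr$channels$torque)
  pre <- tt < 1.0
  # zero commanded torque: recorded torque sits at the passive baseline and
  # the fascicle rests at its passive length
  expect_lt(max(abs(tr$channels$torque$values[pre] -
                      cfg$baseline_torque_nm)), 1e-6)
  gt <- tr$ground_truth
  fpre <- gt$fascicle_true$times < 1.0
  expect_lt(diff(range(gt$fascicle_true$lengths[fpre])), 1e-4)
  # passive length up to the ~2e-6 mm equilibrium of the activation floor
  expect_equal(gt$fascicle_true$lengths[1], cfg$mtu$l_f_rest,
               tolerance = 1e-6)
})

test_that("noise-free MVC plateau matches the quasi-static fixed point", {
  cfg <- quiet_cfg(1, rate_hz = 500)
  mvc <- generate_mvc_trial(cfg)
  gt <- mvc$ground_truth
  tt <- channel_times(gt$torque_clean)
  plateau <- mean(gt$torque_clean$values[tt > 3.5 & tt < 4.5])
  expect_equal(plateau, mvc_torque(cfg$mtu), tolerance = 0.01)
})

test_that("lengthening amplitude equals the SEE force-balance prediction", {
  # quasi-static limit: the fascicle length change between holds is the
  # difference of SEE stretches at the two hold forces (force balance)
  cfg <- quiet_cfg(2, rate_hz = 500)
  p <- cfg$mtu
  mvt <- mvc_torque(p)
  tr <- simulate_trial(cfg, "85-15", seed = 1)
  pred <- steadytorque:::see_stretch(0.85 * mvt, p) -
    steadytorque:::see_stretch(0.15 * mvt, p)
  expect_equal(tr$ground_truth$lengthening_amplitude, pred, tolerance = 0.1)
})

test_that("mechanism: fascicles shorten in development, lengthen in the drop", {
  for (exp in 1:2) {
    cfg <- quiet_cfg(exp, rate_hz = 250)
    conds <- setdiff(names(protocol_library(exp)),
                     c("reference", "15", "30", "45"))
    for (cond in conds) {
      tr <- simulate_trial(cfg, cond, seed = 1)
      gt <- tr$ground_truth
      pb <- gt$trace$phase_boundaries
      f <- gt$fascicle_true
      at <- function(t) f$lengths[which.min(abs(f$times - (gt$onset + t)))]
      # shortening during force development
      expect_lt(at(pb[["hold1_start"]]) - at(0), -1)
      # lengthening during the torque reduction (tendon recoil)
      expect_gt(at(pb[["hold2_start"]]) - at(pb[["hold1_end"]]), 0.5)
    }
  }
})

test_that("Experiment 2 amplitude ordering and Experiment 1 rate ordering hold", {
  cfg2 <- quiet_cfg(2, rate_hz = 250)
  amps <- sapply(c("85-15", "85-30", "85-45"), function(cond)
    simulate_trial(cfg2, cond, seed = 1)$ground_truth$lengthening_amplitude)
  expect_true(amps["85-15"] > amps["85-30"] &&
                amps["85-30"] > amps["85-45"])

  cfg1 <- quiet_cfg(1, rate_hz = 250)
  res <- lapply(c("0.25-s", "0.5-s", "1-s", "2-s"), function(cond) {
    gt <- simulate_trial(cfg1, cond, seed = 1)$ground_truth
    pb <- gt$trace$phase_boundaries
    list(amp = gt$lengthening_amplitude,
         speed = max_lengthening_speed(gt$fascicle_true,
                                       gt$onset + pb[["hold1_end"]],
                                       gt$onset + pb[["hold2_start"]]))
  })
  speeds <- sapply(res, `[[`, "speed")
  expect_true(all(diff(speeds) < 0))  # 0.25-s fastest, 2-s slowest
  # amplitudes differ far less across Exp 1 than across Exp 2 drops
  amps1 <- sapply(res, `[[`, "amp")
  expect_lt(diff(range(amps1)), 0.5 * diff(range(amps)))
})

test_that("controller divergence raises a simulation-failure error", {
  # absurdly slow activation dynamics cannot follow the commanded ramp
  # (a merely weak MTU still tracks, because the trace scales with its MVT)
  sluggish <- mtu_params(activation_tau_up = 5, activation_tau_down = 5)
  cfg <- quiet_cfg(2, rate_hz = 250, mtu = sluggish)
  expect_error(simulate_trial(cfg, "85-15", seed = 1),
               "simulation failure")
})

test_that("generate_dataset is structurally sound and seed-controlled", {
  cfg <- noisy_cfg(1, rate_hz = 200)
  ds <- generate_dataset(cfg, n_subjects = 2, trials_per_condition = 1,
                         conditions = c("reference", "2-s"), seed = 5)
  expect_length(ds, 2)
  expect_identical(ds[[1]]$id, "S01")
  expect_length(ds[[1]]$trials, 2)
  expect_setequal(sapply(ds[[1]]$trials, `[[`, "condition"),
                  c("reference", "2-s"))
  # subjects differ (parameter jitter)
  expect_false(identical(ds[[1]]$mtu$f_max, ds[[2]]$mtu$f_max))
  # reproducible under the same seed; different under another
  ds_b <- generate_dataset(cfg, 2, 1, conditions = c("reference", "2-s"),
                           seed = 5)
  expect_identical(ds, ds_b)
  ds_c <- generate_dataset(cfg, 2, 1, conditions = c("reference", "2-s"),
                           seed = 6)
  expect_false(identical(ds[[1]]$trials[[1]]$channels$torque$values,
                         ds_c[[1]]$trials[[1]]$channels$torque$values))
})

test_that("onset detection on simulated trials lands at the 1% crossing", {
  # the commanded trace leaves zero at 1.5 s; at 20 %MVT/s the 1 %MVT
  # detector threshold is crossed 50 ms later, so the detected onset sits
  # near 1.55 s (detector contract: the threshold-crossing time)
  cfg <- noisy_cfg(1, rate_hz = 500)
  rcfg <- run_config(1)
  ctx <- process_mvc(generate_mvc_trial(cfg, seed = 31), rcfg)
  for (s in 32:34) {
    tr <- simulate_trial(cfg, "reference", seed = s)
    m <- process_trial(tr, ctx, rcfg)
    expect_between(attr(m, "onset"), 1.5, 1.6)
  }
})
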