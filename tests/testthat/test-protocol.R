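# Designed traces, onset detection, matching error, validity gating.

test_that("Experiment 2 test traces reproduce the printed durations", {
  lib <- protocol_library(2)
  tr <- build_desired_trace(lib[["85-15"]])
  pb <- tr$phase_boundaries
  expect_equal(unname(pb["hold1_start"]), 4.25)   # 85 / 20 %MVT/s
  expect_equal(unname(pb["hold1_end"]), 6.5)      # hold1 solved to 2.25 s
  expect_equal(unname(pb["hold2_start"]), 10)     # descend (85-15)/20 = 3.5 s
  expect_equal(unname(pb["hold2_end"]), 15)       # hold2 = 5 s to trace end
  # hold2 durations 5 / 5.75 / 6.5 s; hold1 always 2.25 s
  for (cond in c("85-15", "85-30", "85-45")) {
    pb <- build_desired_trace(lib[[cond]])$phase_boundaries
    expect_equal(unname(pb["hold1_end"] - pb["hold1_start"]), 2.25)
    expect_equal(unname(pb["hold2_end"]), 15)
  }
  expect_equal(unname(
    build_desired_trace(lib[["85-30"]])$phase_boundaries["hold2_start"]), 9.25)
})

test_that("Experiment 1 closure reproduces the printed Hold 2 range", {
  lib <- protocol_library(1)
  h2 <- sapply(c("0.25-s", "0.5-s", "1-s", "2-s"), function(nm) {
    pb <- build_desired_trace(lib[[nm]])$phase_boundaries
    unname(pb["hold2_end"] - pb["hold2_start"])
  })
  # equal-hold closure: hold2 between 4.25 s (2-s drop) and 5.125 s (0.25-s)
  expect_equal(unname(h2["2-s"]), 4.25)
  expect_equal(unname(h2["0.25-s"]), 5.125)
  expect_true(all(h2 >= 4.25 & h2 <= 5.125))
  # reference: single 2-s ramp to 40% then flat to 13.5 s
  ref <- build_desired_trace(lib[["reference"]])
  expect_equal(trace_level(ref, c(1, 2, 8, 13.5)), c(20, 40, 40, 40))
  expect_equal(unname(ref$phase_boundaries["hold2_end"]), 13.5)
})

test_that("trace construction handles degenerate and infeasible protocols", {
  # zero-length descend with equal holds is a valid single-plateau trapezoid
  sp <- protocol_spec(1, "flat", 40, 40, 0)
  tr <- build_desired_trace(sp)
  expect_equal(trace_level(tr, c(3, 10)), c(40, 40))
  expect_true(all(diff(tr$phase_boundaries) >= 0))
  # hold durations that solve negative -> infeasible
  expect_error(
    build_desired_trace(protocol_spec(2, "bad", 85, 15, 3.5,
                                      hold2_duration = 12)),
    "infeasible")
})

test_that("trace integral is invariant to resampling rate", {
  tr <- build_desired_trace(protocol_library(2)[["85-15"]])
  ints <- sapply(c(100, 1000, 5000), function(fs) {
    t <- seq(0, 15, by = 1 / fs)
    # trapezoid rule on a piecewise-linear function is exact at breakpoints;
    # include them to make the quadrature exact at any rate
    t <- sort(unique(c(t, tr$times)))
    v <- trace_level(tr, t)
    sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  })
  expect_lt(max(abs(ints - ints[1])) / abs(ints[1]), 1e-9)
})

test_that("onset detector finds sustained crossings and rejects silence", {
  fs <- 2000
  x <- c(rep(0, 2 * fs), rep(40, 2 * fs))
  on <- detect_contraction_onset(ts_channel(x, fs))
  expect_equal(on, 2.0, tolerance = 1.5 / fs)
  expect_error(detect_contraction_onset(ts_channel(rep(0, fs), fs)),
               "onset not found")
  # a 50-ms blip must not trigger the 100-ms sustain requirement
  blip <- rep(0, 2 * fs); blip[1000:1100] <- 5
  expect_error(detect_contraction_onset(ts_channel(blip, fs)), "not found")
})

test_that("matching error is the max deviation and translation-equivariant", {
  fs <- 200
  tr <- build_desired_trace(protocol_library(1)[["1-s"]])
  t <- seq(0, 15, by = 1 / fs)
  onset <- 0.5
  perfect <- trace_level(tr, t - onset)
  ch <- ts_channel(perfect, fs)
  expect_equal(torque_matching_error(ch, tr, onset), 0, tolerance = 1e-12)
  for (delta in c(5, -3.2))
    expect_equal(
      torque_matching_error(ts_channel(perfect + delta, fs), tr, onset),
      abs(delta), tolerance = 1e-12)
  short <- ts_channel(perfect[t < 10], fs)
  expect_error(torque_matching_error(short, tr, onset), "not covered")
})

test_that("dip threshold reproduces the pilot-derived values", {
  expect_equal(dip_threshold_from_pilot(0.6, 0.1), 0.8)
  expect_equal(dip_threshold_from_pilot(0.8, 0.6), 2.0)
  expect_equal(dip_threshold_from_pilot(1.3, 0), 1.3)
  expect_error(dip_threshold_from_pilot(-1, 0.1), "non-negative")
  expect_equal(validity_rules(1)$dip_threshold, 0.8)
  expect_equal(validity_rules(2)$dip_threshold, 2)
})

test_that("validity gating applies both rules with a strict error bound", {
  fs <- 200
  tr <- build_desired_trace(protocol_library(1)[["1-s"]])
  t <- seq(0, 15, by = 1 / fs)
  onset <- 0.5
  mvt <- 40
  act <- trace_level(tr, t - onset) / 100 * mvt  # Nm, perfect tracking
  rules <- validity_rules(1)
  v <- validate_trial(5, ts_channel(act, fs), tr, onset, rules)
  expect_true(v$valid)
  expect_length(v$reasons, 0)

  # matching error above 10 -> invalid with reason
  v2 <- validate_trial(10.5, ts_channel(act, fs), tr, onset, rules)
  expect_false(v2$valid)
  expect_identical(v2$reasons, "matching_error")

  # undershoot 1 Nm below the Hold 2 mean trips the 0.8-Nm Exp 1 rule
  dip <- act
  i <- which(t > onset + 8 & t < onset + 8.2)  # inside the descend phase
  dip[i] <- mean(act[t > onset + 8.75]) - 1.0
  v3 <- validate_trial(5, ts_channel(dip, fs), tr, onset, rules)
  expect_false(v3$valid)
  expect_true("dip" %in% v3$reasons)
  # but not under the looser Exp 2 threshold: monotone in the threshold
  v4 <- validate_trial(5, ts_channel(dip, fs), tr, onset, validity_rules(2))
  expect_true(v4$valid)

  # exact equality at 10% is kept under the strict '>' rule, with a warning
  expect_warning(
    v5 <- validate_trial(10, ts_channel(act, fs), tr, onset, rules),
    "strict")
  expect_true(v5$valid)
})

test_that("hold windows apply the guard and presets", {
  tr <- build_desired_trace(protocol_library(2)[["85-15"]])
  w <- hold_windows(tr, onset = 1.5)
  expect_equal(w$hold1, 1.5 + c(4.5, 6.25))
  expect_equal(w$hold2, 1.5 + c(10.25, 14.75))
  wf <- hold_windows(tr, onset = 1.5, policy = "fig4")
  expect_equal(wf$hold1, 1.5 + c(5, 6))
  expect_equal(wf$hold2, 1.5 + c(11, 14))
})
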