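test_that("detector matches ground truth and rejects flat traces", {
  a <- simple_archetype(gain = 0.25, rheo = 20)
  ss <- simulate_current_clamp(a, protocol_long_step(140), noise_sd = 0,
                               seed = 1)
  ev <- detect_aps(ss$sweeps[[1]])
  gt <- ss$metadata$spike_times[[1]]
  expect_equal(nrow(ev), 30)
  # events at their planted times: sample-level in the train interior,
  # within the pre-depolarization (< 0.15 ms) at the train edges
  devs <- abs(ev$threshold_time - gt)
  expect_lte(median(devs), 2 * ss$sweeps[[1]]$dt)
  expect_lt(max(devs), 1.5e-4)
  flat <- sweep_trace(dt = 2e-5, voltage = rep(-70, 5000))
  expect_equal(nrow(detect_aps(flat)), 0)
  expect_error(detect_aps(sweep_trace(dt = 2e-5, current = rep(0, 10))),
               "no voltage")
  expect_error(detect_aps(sweep_trace(dt = 1e-3,
                                      voltage = rep(-70, 100))),
               "coarse")
})

test_that("detected count equals insertion count at noise up to 0.5 mV", {
  archs <- archetype_defaults()
  for (nm in names(archs)) {
    for (noise in c(0, 0.3, 0.5)) {
      amps <- c(90, 140)
      ss <- simulate_current_clamp(archs[[nm]],
                                   protocol_long_step(amps),
                                   noise_sd = noise,
                                   seed = 17 + noise * 10, dt = 1e-4)
      for (k in seq_along(amps)) {
        ev <- detect_aps(ss$sweeps[[k]])
        expect_equal(nrow(ev),
                     length(ss$metadata$spike_times[[k]]),
                     label = sprintf("%s %g pA noise %g", nm,
                                     amps[k], noise))
      }
    }
  }
})

test_that("waveform metric estimators are nearly unbiased on templates", {
  # mean absolute error of per-run mean metrics < 5% of the parameter
  a <- e3_spec()
  runs <- vapply(1:25, function(seed) {
    ss <- simulate_current_clamp(a, protocol_long_step(140),
                                 noise_sd = 0.3, seed = seed)
    ev <- detect_aps(ss$sweeps[[1]])
    c(width = mean(ev$width), amp = mean(ev$amplitude),
      repol = mean(ev$repol_duration),
      ahp = mean(ev$ahp_amplitude, na.rm = TRUE))
  }, numeric(4))
  expect_lt(abs(mean(runs["width", ]) - 1.3) / 1.3, 0.05)
  expect_lt(abs(mean(runs["repol", ]) - 0.8) / 0.8, 0.05)
  expect_lt(abs(mean(runs["ahp", ]) - 21.6) / 21.6, 0.05)
  # amplitude declines by design through accommodation; compare with
  # the mean template amplitude over the train
  amp_expect <- 54.6 * (1 - a$accommodation / 2)
  expect_lt(abs(mean(runs["amp", ]) - amp_expect) / amp_expect, 0.05)
})

test_that("firing-pattern features match hand-computed oracles", {
  # perfectly regular 20 Hz: cv = 0, adaptation = 0
  a <- simple_archetype(gain = 0.2, rheo = 40)
  a$isi_cv <- 0; a$adaptation <- 0; a$accommodation <- 0
  ss <- simulate_current_clamp(a, protocol_long_step(c(20, 140)),
                               noise_sd = 0, seed = 2, dt = 1e-4)
  f <- firing_pattern_features(ss)
  expect_equal(f$max_rate, 20)
  expect_lt(f$isi_cv, 0.01)
  expect_lt(abs(f$adaptation_index), 0.01)
  expect_equal(f$rheobase, 140)
  expect_equal(f$burst + f$pause + f$delay, 0)
  # hand-arithmetic oracle for the ISI CV on (50, 100, 200) ms:
  # sd = 76.376, mean = 116.67 -> cv = 0.6547
  isis <- c(50, 100, 200) / 1000
  st <- cumsum(c(0.25, isis))
  expect_equal(sd(isis) / mean(isis), 0.65465, tolerance = 1e-4)
  # delayed archetype raises the delay flag via rheobase latency
  e4 <- archetype_defaults()$E4
  ss4 <- simulate_current_clamp(e4, protocol_long_step(seq(40, 200, 40)),
                                noise_sd = 0.3, seed = 3, dt = 1e-4)
  f4 <- firing_pattern_features(ss4)
  expect_equal(f4$delay, 1)
  expect_gt(f4$latency_rheobase, 100)
  # non-firing cell is flagged
  ss0 <- simulate_current_clamp(a, protocol_long_step(c(10, 20)),
                                seed = 1, dt = 1e-4)
  f0 <- firing_pattern_features(ss0)
  expect_false(f0$firing)
  expect_true(is.na(f0$max_rate))
})

test_that("F-I curve equals ground-truth counts and is monotone", {
  a <- e3_spec()
  prot <- protocol_long_step(seq(0, 200, by = 20))
  ss <- simulate_current_clamp(a, prot, noise_sd = 0, seed = 6,
                               dt = 1e-4)
  fi <- fi_curve(ss)
  gt_rates <- vapply(ss$metadata$spike_times, length, numeric(1)) / 1
  expect_equal(fi$rate, gt_rates[order(prot$step_amplitude)])
  expect_true(all(diff(fi$rate) >= 0))
  # subthreshold-only family: all rates zero
  ss0 <- simulate_current_clamp(a, protocol_long_step(c(0, 10)),
                                seed = 1, dt = 1e-4)
  expect_true(all(fi_curve(ss0)$rate == 0))
})

test_that("failure rate reproduces planted pulse successes exactly", {
  a <- e3_spec()
  prot <- protocol_pulse_train(c(160, 300), pulse_rate = 50,
                               n_pulses = 50)
  ss <- simulate_current_clamp(a, prot, noise_sd = 0.2, seed = 9,
                               dt = 1e-4)
  fr <- failure_rate(ss)
  for (k in 1:2) {
    gt_fail <- 100 * mean(!ss$metadata$success[[k]])
    expect_equal(fr$failure_pct[k], gt_fail)
  }
  # saturating amplitude: every pulse fires
  prot_hi <- protocol_pulse_train(500, pulse_rate = 20, n_pulses = 20)
  ss_hi <- simulate_current_clamp(a, prot_hi, seed = 2, dt = 1e-4)
  expect_equal(failure_rate(ss_hi)$failure_pct, 0)
  # hopeless amplitude: every pulse fails
  prot_lo <- protocol_pulse_train(5, pulse_rate = 20, n_pulses = 20)
  ss_lo <- simulate_current_clamp(a, prot_lo, seed = 2, dt = 1e-4)
  expect_equal(failure_rate(ss_lo)$failure_pct, 100)
})

test_that("passive properties are recovered from the RC relaxation", {
  a <- simple_archetype()
  a$input_resistance <- 200; a$membrane_tau <- 20
  prot <- protocol_long_step(-50, step_onset = 0.2, step_offset = 1.2)
  ss <- simulate_current_clamp(a, prot, noise_sd = 0, seed = 1,
                               dt = 1e-4)
  pp <- passive_properties(ss$sweeps[[1]], pulse_amplitude = -50,
                           pulse_onset = 0.2, pulse_offset = 1.2)
  expect_lt(abs(pp$input_resistance - 200) / 200, 0.01)
  expect_lt(abs(pp$membrane_tau - 20) / 20, 0.01)
  expect_lt(abs(pp$capacitance - 100) / 100, 0.02)
  # linearity: doubling the pulse leaves R unchanged
  prot2 <- protocol_long_step(-100, step_onset = 0.2, step_offset = 1.2)
  ss2 <- simulate_current_clamp(a, prot2, seed = 1, dt = 1e-4)
  pp2 <- passive_properties(ss2$sweeps[[1]], pulse_amplitude = -100,
                            pulse_onset = 0.2, pulse_offset = 1.2)
  expect_equal(pp2$input_resistance, pp$input_resistance,
               tolerance = 0.01)
  # tau recovery within 5% at noise 0.5 mV averaged over seeds
  taus <- vapply(1:20, function(seed) {
    ssn <- simulate_current_clamp(a, prot, noise_sd = 0.5, seed = seed,
                                  dt = 1e-4)
    passive_properties(ssn$sweeps[[1]], pulse_amplitude = -50,
                       pulse_onset = 0.2,
                       pulse_offset = 1.2)$membrane_tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 20) / 20, 0.05)
})
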