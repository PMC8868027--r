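test_that("measured plateaus match the generator closed form", {
  spec <- single_boltzmann(v50 = -10.66, slope = 8, gmax = 40)
  prot <- protocol_vstep_family()
  ss <- simulate_vclamp_family(spec, prot, noise_sd = 0)
  fam <- measure_family(ss)
  gt <- ss$metadata$component_plateau[, 1]
  expect_equal(fam$plateau, gt, tolerance = 1e-3)
  # Boltzmann midpoint: plateau at V = v50 is half of gmax * (V - E)
  v <- prot$step_voltages
  po <- 1 / (1 + exp((-10.66 - v) / 8))
  expect_equal(fam$plateau, 40 * po * (v - (-90)), tolerance = 1e-2)
})

test_that("condition subtraction recovers the sensitive component", {
  spec <- etype3_conductances()
  prot <- protocol_vstep_family()
  ctrl <- measure_family(simulate_vclamp_family(spec, prot))
  # drug identical to control: all-zero difference
  zero <- subtract_conditions(ctrl, ctrl)
  expect_true(all(abs(zero$plateau) < 1e-9))
  expect_equal(zero$condition, "control_sensitive")
  # full block: control - TEA equals the TEA-sensitive component
  spec_full <- spec
  spec_full$block_fraction_tea <- 1
  ss_c <- simulate_vclamp_family(spec_full, prot)
  ss_t <- simulate_vclamp_family(spec_full, prot, condition = "TEA")
  sens <- subtract_conditions(measure_family(ss_c), measure_family(ss_t))
  kv3 <- ss_c$metadata$component_plateau[, 1]
  expect_equal(sens$plateau, kv3, tolerance = 1e-3)
  # 50% block: estimate is half the true component
  ss_h <- simulate_vclamp_family(spec, prot, condition = "TEA")
  half <- subtract_conditions(measure_family(ss_c), measure_family(ss_h))
  expect_equal(half$plateau, 0.5 * kv3, tolerance = 1e-3)
  # mismatched grids are refused
  prot2 <- protocol_vstep_family(step_voltages = seq(-46, 24, by = 10))
  fam2 <- measure_family(simulate_vclamp_family(spec, prot2))
  expect_error(subtract_conditions(ctrl, fam2), "grids differ")
})

test_that("Boltzmann fit recovers V50 exactly on noiseless tails", {
  spec <- single_boltzmann(v50 = -28.18, slope = 8)
  ss <- simulate_vclamp_family(spec, protocol_vstep_family())
  fit <- fit_activation(measure_family(ss))
  expect_equal(fit$v50, -28.18, tolerance = 0.01)
  expect_equal(fit$slope, 8, tolerance = 0.05)
  # half-activation property of the fitted curve
  expect_equal(predict(fit, -28.18), fit$imax / 2, tolerance = 1e-6)
  # voltage-shift equivariance
  spec2 <- single_boltzmann(v50 = -18.18, slope = 8)
  fit2 <- fit_activation(measure_family(
    simulate_vclamp_family(spec2, protocol_vstep_family())))
  expect_equal(fit2$v50 - fit$v50, 10, tolerance = 0.05)
  # fitted activation curve is monotone in V
  vv <- seq(-80, 40, by = 1)
  expect_true(all(diff(predict(fit, vv)) >= 0))
})

test_that("V50 recovery stays unbiased at moderate tail noise", {
  spec <- single_boltzmann(v50 = -28.18, slope = 8, gmax = 40)
  errs <- vapply(1:10, function(seed) {
    ss <- simulate_vclamp_family(spec, protocol_vstep_family(),
                                 noise_sd = 5, seed = seed)
    fit_activation(measure_family(ss))$v50 - (-28.18)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("extra-sum-of-squares F test separates shifted activation curves", {
  prot <- protocol_vstep_family()
  base <- single_boltzmann(v50 = -28.18, slope = 8, gmax = 40)
  shifted <- single_boltzmann(v50 = -10.66, slope = 8, gmax = 40)
  # identical data: F ~ 0, p ~ 1
  fam <- measure_family(simulate_vclamp_family(base, prot))
  same <- compare_activation_fits(fam, fam)
  expect_lt(same$F, 1e-6)
  expect_gt(same$p, 0.99)
  # an 18-mV shift at low noise is detected in every run
  ps <- vapply(1:20, function(seed) {
    fa <- measure_family(simulate_vclamp_family(base, prot,
                                                noise_sd = 3,
                                                seed = seed))
    fb <- measure_family(simulate_vclamp_family(shifted, prot,
                                                noise_sd = 3,
                                                seed = seed + 1000))
    compare_activation_fits(fa, fb)$p
  }, numeric(1))
  expect_true(all(ps < 0.01))
})

test_that("F test keeps its nominal type-I error under the null", {
  prot <- protocol_vstep_family()
  base <- single_boltzmann(v50 = -28.18, slope = 8, gmax = 40)
  n_sim <- 500
  rej <- vapply(seq_len(n_sim), function(seed) {
    fa <- measure_family(simulate_vclamp_family(base, prot,
                                                noise_sd = 8,
                                                seed = 2 * seed))
    fb <- measure_family(simulate_vclamp_family(base, prot,
                                                noise_sd = 8,
                                                seed = 2 * seed + 1))
    p <- tryCatch(compare_activation_fits(fa, fb)$p,
                  error = function(e) NA_real_)
    !is.na(p) && p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
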