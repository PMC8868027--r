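test_that("long-step spike counts follow the F-I rule exactly", {
  a <- simple_archetype(gain = 0.25, rheo = 20)
  ss <- simulate_current_clamp(a, protocol_long_step(140), noise_sd = 0,
                               seed = 1)
  expect_length(ss$metadata$spike_times[[1]], 30)  # 0.25 * (140 - 20)
  # subthreshold step elicits nothing
  ss0 <- simulate_current_clamp(a, protocol_long_step(10), seed = 1)
  expect_length(ss0$metadata$spike_times[[1]], 0)
  expect_error(simulate_current_clamp(a, protocol_long_step(140),
                                      noise_sd = -1), "negative")
  expect_error(simulate_current_clamp(
    a, protocol_vstep_family()), "mismatch")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- e3_spec()
  s1 <- simulate_current_clamp(a, protocol_long_step(c(60, 140)),
                               noise_sd = 0.3, seed = 7, dt = 1e-4)
  s2 <- simulate_current_clamp(a, protocol_long_step(c(60, 140)),
                               noise_sd = 0.3, seed = 7, dt = 1e-4)
  expect_identical(s1$sweeps[[2]]$voltage, s2$sweeps[[2]]$voltage)
  v1 <- simulate_vclamp_family(etype3_conductances(),
                               protocol_vstep_family(), noise_sd = 5,
                               seed = 3)
  v2 <- simulate_vclamp_family(etype3_conductances(),
                               protocol_vstep_family(), noise_sd = 5,
                               seed = 3)
  expect_identical(v1$sweeps[[4]]$current, v2$sweeps[[4]]$current)
  p1 <- simulate_population(c(2, 2, 2, 2), seed = 5)
  p2 <- simulate_population(c(2, 2, 2, 2), seed = 5)
  expect_identical(p1$cells[[3]]$sweeps[[5]]$voltage,
                   p2$cells[[3]]$sweeps[[5]]$voltage)
  expect_identical(p1$labels, p2$labels)
})

test_that("vclamp family obeys Boltzmann midpoint and additivity", {
  prot <- protocol_vstep_family(step_voltages = c(-56, -36, -28.18,
                                                  -16, -6, 4, 14, 24))
  spec <- single_boltzmann(v50 = -28.18, slope = 8, gmax = 10)
  ss <- simulate_vclamp_family(spec, prot)
  gt <- ss$metadata$component_plateau[, 1]
  # at V = v50 the plateau is half of gmax * (V - E)
  expect_equal(gt[3], 0.5 * 10 * (-28.18 - (-90)), tolerance = 1e-9)
  # additivity: blocked family + sensitive component = control
  mix <- etype3_conductances()
  mix$block_fraction_tea <- 1
  ctrl <- simulate_vclamp_family(mix, prot)
  tea <- simulate_vclamp_family(mix, prot, condition = "TEA")
  kv3 <- ctrl$metadata$component_plateau[, 1]
  expect_equal(measure_family(tea)$plateau + kv3,
               measure_family(ctrl)$plateau, tolerance = 1e-3)
  expect_error(simulate_vclamp_family(spec, protocol_long_step(100)),
               "vstep_family")
})

test_that("PSC generator plants amplitudes, PPR and spontaneous events", {
  spec <- psc_spec(evoked_amplitude = 100, ppr = 0.684, spont_rate = 0)
  prot <- protocol_psc(c(0.1, 0.2), holding = 0)
  ss <- simulate_psc_recording(spec, prot)
  expect_equal(ss$metadata$evoked_amplitudes, c(100, 68.4))
  expect_length(ss$metadata$spont_times, 0)
  # spontaneous Poisson count is reproducible and near rate * duration
  prot2 <- protocol_psc(9.5, holding = 0, duration = 10)
  sp <- simulate_psc_recording(psc_spec(evoked_amplitude = 0,
                                        spont_rate = 3),
                               prot2, seed = 2)
  expect_gt(length(sp$metadata$spont_times), 10)
  # polarity: holding -56 gives inward (negative) deflections
  ep <- psc_spec(evoked_amplitude = 80, spont_rate = 0, holding = -56)
  se <- simulate_psc_recording(ep, protocol_psc(0.1, holding = -56))
  expect_lt(min(se$sweeps[[1]]$current), -60)
})

test_that("pulse-train generator stores per-pulse ground truth", {
  a <- e3_spec()
  prot <- protocol_pulse_train(300, pulse_rate = 50, n_pulses = 20)
  ss <- simulate_current_clamp(a, prot, seed = 4, dt = 1e-4)
  succ <- ss$metadata$success[[1]]
  expect_length(succ, 20)
  expect_length(ss$metadata$spike_times[[1]], sum(succ))
})

test_that("object fields plant exact colocalization counts", {
  fld <- simulate_object_field(n_boutons = 20, n_puncta = 50,
                               planted_coloc_fraction = 0.14, seed = 2)
  planted <- attr(fld, "planted_inside")
  expect_equal(sum(planted), round(0.14 * 50))
  cl <- colocalize_objects(fld)
  expect_equal(which(cl$punctum_colocalized), which(planted))
  expect_error(simulate_object_field(n_boutons = 500, n_puncta = 10,
                                     planted_coloc_fraction = 0.5,
                                     seed = 1, field_size = 8),
               "infeasible|crowded")
})

test_that("population separation scalar collapses structure at zero", {
  pop <- simulate_population(c(6, 6, 6, 6), seed = 3, separation = 0)
  feats <- do.call(rbind, lapply(pop$cells, firing_pattern_features))
  seven <- feats[, c("cell_id", "max_rate", "adaptation_index",
                     "isi_cv", "accommodation", "burst", "pause",
                     "delay")]
  suppressWarnings({
    z <- normalize_features(seven)
    km <- fit_kmeans(z, 4, seed = 3)
  })
  expect_lt(abs(adjusted_rand_index(km$cluster, pop$labels)), 0.2)
})
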