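test_that("endpoint polar profile: angles, bins and KDE normalization", {
  # single endpoint at (10, 0): angle 0, bin [0,45) mean length 10
  nodes <- data.frame(id = 1:2, type = c(1, 3), x = c(0, 10),
                      y = 0, z = 0, radius = c(5, 1), parent = c(-1, 1))
  p <- endpoint_polar_profile(morphology(nodes))
  expect_equal(p$endpoint_angles, 0)
  expect_equal(p$bin_mean_length[1], 10)
  expect_true(all(p$bin_mean_length[-1] == 0))
  # KDE integrates to 1 over the circle
  expect_equal(sum(p$kde$density) * pi / 180, 1, tolerance = 1e-6)

  # degenerate von Mises: all endpoint angles at the bias direction
  m <- simulate_morphology(112.5, Inf, n_endpoints = 6, seed = 1)
  pm <- endpoint_polar_profile(m)
  expect_true(all(abs(pm$endpoint_angles - 112.5) < 1e-6))
  # KDE mode falls in the ventral-root sector
  mode <- pm$kde$angle[which.max(pm$kde$density)]
  expect_true(mode >= 90 && mode < 135)
})

test_that("endpoint angle estimator recovers the planted mean direction", {
  for (bias in c(30, 112.5, 300)) {
    m <- simulate_morphology(bias, 6, n_endpoints = 60,
                             seed = round(bias))
    p <- endpoint_polar_profile(m)
    th <- p$endpoint_angles * pi / 180
    mean_dir <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
    delta <- abs(((mean_dir - bias + 180) %% 360) - 180)
    expect_lt(delta, 5)
  }
})

test_that("uniform trees show no angular concentration (Rayleigh)", {
  # independent primaries so the endpoint angles are uncorrelated
  # (shared lineage in a branched tree correlates endpoint angles and
  # would invalidate the independence assumption of the test)
  m <- simulate_morphology(0, 0, n_endpoints = 200, seed = 9,
                           n_primary = 200)
  p <- endpoint_polar_profile(m)
  rt <- rayleigh_test(p$endpoint_angles)
  expect_gt(rt$p_value, 0.05)
  # and a strongly biased tree is detected
  mb <- simulate_morphology(45, 8, n_endpoints = 200, seed = 9,
                            n_primary = 200)
  expect_lt(rayleigh_test(
    endpoint_polar_profile(mb)$endpoint_angles)$p_value, 1e-4)
})

test_that("Sholl profile: unbranched neurite, binary tree, oracle", {
  # unbranched 100-um radial neurite: one crossing below 100 um,
  # ramification index 1
  nodes <- data.frame(id = 1:11, type = c(1, rep(3, 10)),
                      x = seq(0, 100, by = 10), y = 0, z = 0,
                      radius = c(5, rep(1, 10)),
                      parent = c(-1, 1:10))
  sp <- sholl_profile(morphology(nodes), radius_step = 10)
  expect_true(all(sp$intersections[sp$radii < 100] == 1))
  expect_equal(sp$ramification_index, 1)

  # symmetric binary tree of depth d: the outermost shell is crossed
  # by 2^d branches
  for (d in 2:4) {
    tree <- symmetric_binary_tree(d)
    spd <- sholl_profile(tree, radius_step = 10)
    expect_equal(max(spd$intersections), 2^d)
  }

  # exact segment-circle algorithm matches the arc-sampling oracle
  for (seed in 1:20) {
    m <- simulate_morphology(runif(1, 0, 360), runif(1, 0, 4),
                             n_endpoints = 12, seed = seed)
    spm <- sholl_profile(m, radius_step = 10)
    brute <- sholl_brute_force(m, spm$radii)
    expect_equal(spm$intersections, brute)
  }
})

test_that("critical value is the densest constructed shell", {
  # two primaries; one branches into 4 between 40 and 60 um
  nodes <- data.frame(
    id = 1:9, type = c(1, rep(3, 8)),
    x = c(0, 45, -45, 90, 88, 92, 88, -90, -95),
    y = c(0, 0, 0, 20, -20, 10, -8, 5, -5),
    z = 0, radius = c(5, rep(1, 8)),
    parent = c(-1, 1, 1, 2, 2, 2, 2, 3, 3))
  sp <- sholl_profile(morphology(nodes), radius_step = 10)
  expect_equal(sp$critical_value, 50)
  expect_equal(max(sp$intersections), 6)
  expect_equal(sp$ramification_index, 3)
})

test_that("VRP classification follows the planted projection bias", {
  # ventro-lateral bias into the 90-135 sector -> VRP
  m_vrp <- simulate_morphology(112.5, 12, n_endpoints = 20, seed = 3)
  expect_true(classify_vrp(endpoint_polar_profile(m_vrp)))
  # dorsal bias (E3-like) -> not VRP
  m_dorsal <- simulate_morphology(330, 12, n_endpoints = 20, seed = 3)
  expect_false(classify_vrp(endpoint_polar_profile(m_dorsal)))
  # empty sector -> false
  p <- endpoint_polar_profile(m_dorsal)
  expect_false(classify_vrp(p, sector = c(170, 190)))
})

test_that("perisomatic band has the closed-form area and topology", {
  circ <- l7ephys:::circle_polygon(c(0, 0), 10, n = 256)
  band <- perisomatic_band_roi(circ, r_out = 2, r_in = 1)
  expect_equal(band$area, pi * (12^2 - 9^2), tolerance = 0.01 * band$area)
  # the band contains the original perimeter curve
  expect_true(all(band_contains(band, circ)))
  # points well inside the eroded core or far outside are excluded
  expect_false(band_contains(band, matrix(c(0, 0), 1)))
  expect_false(band_contains(band, matrix(c(20, 0), 1)))
  expect_false(band$eroded_empty)
  # a sliver thinner than 2 um collapses under erosion, with warning
  sliver <- cbind(c(0, 30, 30, 0), c(0, 0, 0.8, 0.8))
  expect_warning(bs <- perisomatic_band_roi(sliver), "annihilates")
  expect_true(bs$eroded_empty)
  expect_gt(bs$area, 0)
})

test_that("colocalization recovers planted fractions exactly", {
  for (frac in c(0, 0.14, 1)) {
    fld <- simulate_object_field(n_boutons = 25, n_puncta = 200,
                                 planted_coloc_fraction = frac,
                                 seed = 21)
    cl <- colocalize_objects(fld)
    expect_equal(cl$pct_puncta, 100 * frac)
  }
  # every punctum inside one bouton
  b <- list(l7ephys:::circle_polygon(c(5, 5), 3, 16),
            l7ephys:::circle_polygon(c(15, 15), 3, 16))
  pts <- cbind(runif(20, 3.5, 6.5), runif(20, 3.5, 6.5))
  cl <- colocalize_objects(object_field(b, pts))
  expect_equal(cl$pct_puncta, 100)
  expect_equal(cl$pct_boutons, 50)
  # disjoint geometry
  far <- object_field(b, cbind(c(30, 40), c(30, 40)))
  cl0 <- colocalize_objects(far)
  expect_equal(cl0$pct_puncta, 0)
  expect_equal(cl0$pct_boutons, 0)
})

test_that("band restriction filters the object denominators", {
  perim <- l7ephys:::circle_polygon(c(25, 25), 10, n = 64)
  band <- perisomatic_band_roi(perim)
  # one bouton on the perimeter (in band), one at the centre (not)
  b_in <- l7ephys:::circle_polygon(c(35, 25), 1, 16)
  b_out <- l7ephys:::circle_polygon(c(25, 25), 1, 16)
  pts <- rbind(c(35, 25), c(25, 25), c(45, 45))
  fld <- object_field(list(b_in, b_out), pts)
  cl <- colocalize_objects(fld, band = band)
  expect_equal(cl$n_boutons, 1)
  expect_equal(cl$n_puncta, 1)
  expect_equal(cl$pct_puncta, 100)
})
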