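blob_features <- function(n_per = 20, k = 4, sep = 6, seed = 2,
                          p = 7) {
  # equidistant isotropic Gaussian blobs (orthogonal centres) in p
  # dimensions, so every cluster merge costs the same
  set.seed(seed)
  centers <- matrix(0, k, p)
  centers[cbind(seq_len(k), seq_len(k))] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[j, ], "+")))
  df <- as.data.frame(x)
  df$cell_id <- sprintf("c%03d", seq_len(nrow(df)))
  list(features = df, labels = rep(seq_len(k), each = n_per))
}

test_that("z-scoring centres, scales, drops constants and replays", {
  f <- data.frame(cell_id = c("a", "b", "c"),
                  x = c(1, 2, 3), y = c(10, 10, 10), z = c(0, 1, 1))
  expect_warning(zn <- normalize_features(f), "zero-variance")
  expect_false("y" %in% names(zn))
  expect_equal(mean(zn$x), 0)
  expect_equal(sd(zn$x), 1)
  # two-cell table: sample-SD convention gives +/- 1/sqrt(2)
  f2 <- data.frame(x = c(1, 3))
  z2 <- normalize_features(f2)
  expect_equal(z2$x, c(-1, 1) / sqrt(2))
  # replay on held-out data reuses the stored parameters
  z_new <- suppressWarnings(
    normalize_features(data.frame(cell_id = "d", x = 4, z = 1,
                                  y = 10),
                       center = attr(zn, "center"),
                       scale = attr(zn, "scale")))
  expect_equal(z_new$x, (4 - 2) / 1)
})

test_that("k-means recovers planted blobs and k = 1 gives total SS", {
  b <- blob_features()
  suppressWarnings({
    km1 <- fit_kmeans(b$features, 1, seed = 1)
    tot <- sum(scale(as.matrix(b$features[, 1:7]), scale = FALSE)^2)
    expect_equal(km1$tot.withinss, tot, tolerance = 1e-8)
    km4 <- fit_kmeans(b$features, 4, seed = 1)
  })
  expect_equal(adjusted_rand_index(km4$cluster, b$labels), 1)
  expect_error(fit_kmeans(b$features, 1000), "k >")
  # determinism under seed
  suppressWarnings({
    a1 <- fit_kmeans(b$features, 4, seed = 9)
    a2 <- fit_kmeans(b$features, 4, seed = 9)
  })
  expect_identical(a1$cluster, a2$cluster)
})

test_that("inertia decreases with k and elbow finds a constructed kink", {
  b <- blob_features()
  suppressWarnings(
    inertia <- vapply(1:8, function(k)
      fit_kmeans(b$features, k, seed = k)$tot.withinss, numeric(1)))
  expect_true(all(diff(inertia) <= 1e-8))
  # piecewise-linear curve with a kink at k = 4
  kink <- data.frame(k = 1:8, inertia = c(100, 75, 50, 25, 23, 21,
                                          19, 17))
  expect_equal(select_k_elbow(kink), 4)
  # geometric decay carries no elbow: warning and k = 1
  geo <- data.frame(k = 1:8, inertia = 100 * 0.5^(0:7))
  expect_warning(kg <- select_k_elbow(geo), "no elbow")
  expect_equal(kg, 1L)
  expect_error(select_k_elbow(data.frame(k = 1:2,
                                         inertia = c(2, 1))),
               "k_max")
})

test_that("PCA projection explains variance correctly", {
  # collinear data: one component carries everything
  line <- data.frame(x = 1:10, y = 2 * (1:10), z = -0.5 * (1:10))
  p <- pca_project(line, 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  expect_error(pca_project(line, 5), "n_components")
  # planted blobs whose centres span a plane stay separated in the
  # 2-D projection
  set.seed(5)
  sq <- as.matrix(expand.grid(c(-6, 6), c(-6, 6)))
  labels <- rep(1:4, each = 20)
  x <- matrix(rnorm(80 * 7), 80, 7)
  x[, 1] <- x[, 1] + sq[labels, 1]
  x[, 2] <- x[, 2] + sq[labels, 2]
  b <- list(features = as.data.frame(x), labels = labels)
  pp <- pca_project(b$features, 2)
  sil <- vapply(seq_len(nrow(pp$scores)), function(i) {
    d <- sqrt(rowSums(sweep(pp$scores, 2, pp$scores[i, ])^2))
    own <- mean(d[b$labels == b$labels[i]][-which(
      which(b$labels == b$labels[i]) == i)])
    other <- min(vapply(setdiff(unique(b$labels), b$labels[i]),
                        function(l) mean(d[b$labels == l]),
                        numeric(1)))
    (other - own) / max(own, other)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("e-type model object supports the standard S3 interface", {
  b <- blob_features()
  m <- suppressWarnings(fit_etype_model(b$features, k_max = 8,
                                        seed = 1))
  expect_s3_class(m, "etype_model")
  expect_equal(m$k, 4)
  expect_equal(adjusted_rand_index(m$labels, b$labels), 1)
  expect_output(print(m), "etype_model")
  expect_output(summary(m), "explained variance")
  # predict assigns training cells back to their own clusters
  pred <- predict(m, b$features)
  expect_equal(pred, unname(m$labels))
})

test_that("waveform crosstab separates planted template shapes", {
  # two cell groups with very different spike shapes
  fast <- e3_spec()
  slow <- archetype_defaults()$E2
  prot <- protocol_long_step(c(60, 140))
  cells <- c(lapply(1:6, function(s)
    simulate_current_clamp(fast, prot, noise_sd = 0.2, seed = s,
                           dt = 1e-4)),
    lapply(7:12, function(s)
      simulate_current_clamp(slow, prot, noise_sd = 0.2, seed = s,
                             dt = 1e-4)))
  et <- rep(c("F", "S"), each = 6)
  ct <- waveform_types_crosstab(cells, et, k_wave = 2, seed = 1)
  expect_equal(adjusted_rand_index(ct$ap_labels,
                                   rep(1:2, each = 6)), 1)
  # columns are percentages summing to 100 per e-type
  expect_equal(unname(colSums(ct$percentages)), c(100, 100))
})
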