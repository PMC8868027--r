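#' Z-score normalization of a feature table
#'
#' Each feature column is centred and scaled to unit sample SD; binary
#' flag columns are scaled identically (the convention can be switched
#' off to keep flags raw 0/1). Zero-variance columns are dropped with a
#' warning. The column means and SDs are stored so held-out cells can
#' be normalized identically.
#'
#' @param features Data frame (a `cell_id` column is carried through
#'   unscaled).
#' @param scale_binary Scale 0/1 flag columns like continuous ones.
#' @param center,scale Optional stored parameters from a previous call
#'   (normalization replay).
#' @return Normalized data frame with attributes `center`, `scale` and
#'   `dropped`.
#' @export
normalize_features <- function(features, scale_binary = TRUE,
                               center = NULL, scale = NULL) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  if (is.null(center) && nrow(features) < 2)
    stop("need >= 2 cells to estimate normalization parameters")
  id <- features[["cell_id"]]
  x <- features[setdiff(names(features), "cell_id")]
  x <- x[vapply(x, is.numeric, TRUE)]
  if (!all(vapply(x, function(c) all(is.finite(c)), TRUE)))
    stop("non-finite feature values")
  binary <- vapply(x, function(c) all(c %in% c(0, 1)), TRUE)
  if (is.null(center)) {
    center <- vapply(x, mean, numeric(1))
    scale <- vapply(x, stats::sd, numeric(1))
    if (!scale_binary) {
      center[binary] <- 0
      scale[binary] <- 1
    }
  }
  dropped <- names(x)[scale == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[setdiff(names(x), dropped)]
  }
  keep <- names(x)
  z <- as.data.frame(mapply(function(c, m, s) (c - m) / s,
                            x, center[keep], scale[keep],
                            SIMPLIFY = FALSE))
  if (!is.null(id)) z <- cbind(cell_id = id, z)
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  attr(z, "dropped") <- dropped
  z
}

feature_matrix <- function(features) {
  as.matrix(features[setdiff(names(features),
                             "cell_id")][vapply(
    features[setdiff(names(features), "cell_id")], is.numeric, TRUE)])
}

#' K-means clustering of normalized features
#'
#' Lloyd's algorithm with `n_restarts` random restarts, keeping the
#' solution with the smallest within-cluster sum of squares;
#' deterministic under `seed`.
#'
#' @param features Normalized feature data frame (see
#'   [normalize_features()]).
#' @param k Number of clusters (`1 <= k <=` number of cells).
#' @param seed RNG seed (local to this call).
#' @param n_restarts Random restarts.
#' @return A `stats::kmeans` object.
#' @export
fit_kmeans <- function(features, k, seed = 1, n_restarts = 10) {
  x <- feature_matrix(features)
  if (k > nrow(x)) stop("k > number of cells")
  with_seed(seed, {
    best <- NULL
    attempts <- 0
    while (attempts < max(n_restarts, 1) * 5 &&
           (is.null(best) || attempts < n_restarts)) {
      attempts <- attempts + 1
      init <- x[sample.int(nrow(x), k), , drop = FALSE]
      fit <- tryCatch(
        stats::kmeans(x, centers = init, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL)  # empty cluster under Lloyd: resample
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
    if (is.null(best))  # pathological inits throughout: robust fallback
      best <- stats::kmeans(x, centers = k, nstart = n_restarts,
                            iter.max = 100)
    best
  })
}

#' Elbow selection of the cluster number
#'
#' Returns the k at maximum discrete curvature (second difference) of
#' the inertia curve, ties broken toward the smaller k. A structure
#' check guards the degenerate case: if log-inertia is nearly linear in
#' k (monotone geometric decay, i.e. no elbow), a warning is issued and
#' k = 1 reported.
#'
#' @param inertia_curve Data frame with columns `k` and `inertia`
#'   (non-increasing), covering `k = 1..k_max` with `k_max >= 3`.
#' @param r2_null Log-linearity threshold above which the curve is
#'   declared structureless.
#' @return Selected k (integer).
#' @export
select_k_elbow <- function(inertia_curve, r2_null = 0.995) {
  stopifnot(all(c("k", "inertia") %in% names(inertia_curve)))
  kk <- inertia_curve$k
  w <- inertia_curve$inertia
  if (max(kk) < 3) stop("k_max must be at least 3")
  if (all(w > 0)) {
    fit <- stats::lm(log(w) ~ kk)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > r2_null) {
      warning("inertia curve shows no elbow structure; returning k = 1")
      return(1L)
    }
  }
  # curvature on the scale-invariant (relative) inertia
  wn <- w / w[1]
  d2 <- wn[seq_len(length(wn) - 2)] - 2 * wn[seq(2, length(wn) - 1)] +
    wn[seq(3, length(wn))]
  kk[which.max(d2) + 1L]
}

#' PCA projection of a normalized feature table
#'
#' @param features Normalized feature data frame.
#' @param n_components Number of components to retain.
#' @return List with `scores` (cells x n_components),
#'   `explained_variance` (fractions, ordered) and `rotation`.
#' @export
pca_project <- function(features, n_components = 2) {
  x <- feature_matrix(features)
  if (n_components > ncol(x)) stop("n_components > number of features")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE])
}

#' Fit the e-type classification model
#'
#' End-to-end e-typing of a per-cell feature table: z-score
#' normalization, k-means over `k = 1..k_max` to build the inertia
#' (elbow) curve, elbow selection of k (unless `k` is given), final
#' clustering and 2-D PCA projection for visualization.
#'
#' @param features Raw per-cell feature data frame (seven firing
#'   features; a `cell_id` column is carried through).
#' @param k Cluster count; `NULL` selects by elbow.
#' @param k_max Largest k scanned for the inertia curve.
#' @param n_restarts Restarts per k.
#' @param seed RNG seed.
#' @param scale_binary Passed to [normalize_features()].
#' @return Object of class `"etype_model"`: `k`, `centroids`
#'   (normalized units), `labels`, `inertia_curve`, `pca_scores`,
#'   `explained_variance`, `feature_means`, `feature_sds`.
#' @export
fit_etype_model <- function(features, k = NULL, k_max = 8,
                            n_restarts = 10, seed = 1,
                            scale_binary = TRUE) {
  z <- normalize_features(features, scale_binary = scale_binary)
  n <- nrow(z)
  k_scan <- seq_len(min(k_max, n - 1))
  fits <- lapply(k_scan, function(kk)
    fit_kmeans(z, kk, seed = seed + kk, n_restarts = n_restarts))
  curve <- data.frame(k = k_scan,
                      inertia = vapply(fits, `[[`, numeric(1),
                                       "tot.withinss"))
  k_sel <- if (is.null(k)) select_k_elbow(curve) else k
  fit <- if (k_sel %in% k_scan) fits[[match(k_sel, k_scan)]]
         else fit_kmeans(z, k_sel, seed = seed, n_restarts = n_restarts)
  pca <- pca_project(z, 2)
  structure(list(k = k_sel, centroids = fit$centers,
                 labels = fit$cluster, inertia = fit$tot.withinss,
                 inertia_curve = curve, pca_scores = pca$scores,
                 explained_variance = pca$explained_variance,
                 feature_means = attr(z, "center"),
                 feature_sds = attr(z, "scale"),
                 cell_id = features[["cell_id"]],
                 features = z),
            class = "etype_model")
}

#' @export
print.etype_model <- function(x, ...) {
  cat(sprintf("<etype_model> k = %d over %d cells, %d features\n",
              x$k, length(x$labels), ncol(x$centroids)))
  cat("cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.etype_model <- function(object, ...) {
  cat(sprintf("E-type model: k = %d (elbow over k = 1..%d)\n",
              object$k, max(object$inertia_curve$k)))
  cat(sprintf("within-cluster SS: %.3f (of total %.3f)\n",
              object$inertia, object$inertia_curve$inertia[1]))
  cat(sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
              100 * object$explained_variance[1],
              100 * object$explained_variance[2]))
  print(round(object$centroids, 2))
  invisible(object)
}

#' @export
plot.etype_model <- function(x, ...) {
  graphics::plot(x$pca_scores, col = x$labels, pch = 19,
                 xlab = sprintf("PC1 (%.0f%%)",
                                100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.0f%%)",
                                100 * x$explained_variance[2]),
                 main = sprintf("e-types (k = %d)", x$k), ...)
  invisible(x)
}

#' Assign new cells to fitted e-types
#'
#' @param object An `"etype_model"`.
#' @param newdata Raw feature data frame with the model's feature
#'   columns.
#' @param ... Unused.
#' @return Integer cluster labels.
#' @export
predict.etype_model <- function(object, newdata, ...) {
  keep <- colnames(object$centroids)
  z <- mapply(function(f, m, s) (newdata[[f]] - m) / s, keep,
              object$feature_means[keep], object$feature_sds[keep])
  z <- matrix(z, ncol = length(keep))
  d <- apply(z, 1, function(row)
    which.min(colSums((t(object$centroids) - row)^2)))
  as.integer(d)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' AP-waveform typing and e-type cross-tabulation
#'
#' Extracts the first AP at rheobase for every cell (window 1 ms
#' pre-threshold to 10 ms post-threshold), resamples it to
#' `n_points`, normalizes amplitude so shape rather than size
#' clusters, k-means clusters the waveforms into AP-types and
#' cross-tabulates AP-types against e-types as column percentages.
#'
#' @param sweepsets List of long-step [sweep_set()]s (one per cell).
#' @param etype_labels E-type label per cell.
#' @param k_wave Number of AP-types.
#' @param seed RNG seed.
#' @param n_points Resampled waveform length.
#' @param ... Passed to [detect_aps()].
#' @return List with `ap_labels` (per firing cell), `percentages`
#'   (AP-type x e-type matrix, columns summing to 100), `waveforms`
#'   (matrix of normalized waveforms) and `excluded` (non-firing cell
#'   indices, dropped with a warning).
#' @export
waveform_types_crosstab <- function(sweepsets, etype_labels, k_wave = 4,
                                    seed = 1, n_points = 200, ...) {
  stopifnot(length(sweepsets) == length(etype_labels))
  wf <- vector("list", length(sweepsets))
  for (i in seq_along(sweepsets)) {
    ss <- sweepsets[[i]]
    prot <- ss$protocol
    amps <- prot$step_amplitude
    ev1 <- NULL
    for (k in order(amps)) {
      ev <- detect_aps(ss$sweeps[[k]], ...)
      ev <- ev[ev$threshold_time >= prot$step_onset &
                 ev$threshold_time <= prot$step_offset, ]
      if (nrow(ev)) {
        t <- sweep_times(ss$sweeps[[k]])
        v <- ss$sweeps[[k]]$voltage
        t0 <- ev$threshold_time[1]
        grid <- seq(t0 - 0.001, t0 + 0.010, length.out = n_points)
        w <- stats::approx(t, v, xout = grid, rule = 2)$y
        w <- w - w[1]
        rng <- max(w) - min(w)
        if (rng > 0) w <- w / rng
        ev1 <- w
        break
      }
    }
    wf[[i]] <- ev1
  }
  excluded <- which(vapply(wf, is.null, TRUE))
  if (length(excluded))
    warning("excluding non-firing cell(s): ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(seq_along(wf), excluded)
  m <- do.call(rbind, wf[keep])
  km <- fit_kmeans(as.data.frame(m), k_wave, seed = seed,
                   n_restarts = 10)
  et <- factor(etype_labels[keep])
  tab <- table(ap_type = km$cluster, e_type = et)
  pct <- sweep(tab, 2, colSums(tab), "/") * 100
  list(ap_labels = km$cluster, percentages = pct,
       waveforms = m, excluded = excluded)
}
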