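# Synthetic morphology and segmented-object generators with planted
# ground truth for the polar-profile and colocalization analyses.

# Best & Fisher (1979) rejection sampler for the von Mises
# distribution; kappa = 0 degenerates to circular uniform,
# kappa = Inf to a point mass at mu. Angles in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 2 * pi))
  if (!is.finite(kappa)) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform angular distribution against a
#' unimodal alternative via the mean resultant length.
#'
#' @param angles_deg Angles in degrees.
#' @return List with `r_bar` (mean resultant length), `statistic`
#'   (Z = n r_bar^2) and `p_value` (with the standard small-sample
#'   correction).
#' @export
rayleigh_test <- function(angles_deg) {
  th <- angles_deg * pi / 180
  n <- length(th)
  r_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r_bar = r_bar, statistic = z, p_value = max(0, min(1, p)))
}

#' Simulate a direction-biased neurite tree
#'
#' Grows a random tree rooted at the soma; every segment direction is
#' drawn from a von Mises distribution centred on `bias_direction`, so
#' endpoint angles concentrate around the bias as
#' `bias_concentration` grows (uniform at 0, degenerate at `Inf`).
#' Trees are planar (z = 0), matching the slice-plane analyses.
#'
#' @param bias_direction Mean growth direction (degrees, 0 along +x,
#'   counterclockwise).
#' @param bias_concentration Von Mises concentration (>= 0).
#' @param n_endpoints Number of terminal tips (>= 1).
#' @param seed Optional RNG seed (local to this call).
#' @param segment_length Mean segment length (micrometres).
#' @param n_primary Number of primary neurites leaving the soma.
#' @return A [morphology()]; endpoint ground-truth angles (degrees)
#'   are stored in `attr(, "planted_angles")`.
#' @export
simulate_morphology <- function(bias_direction = 0,
                                bias_concentration = 4,
                                n_endpoints = 10, seed = NULL,
                                segment_length = 20, n_primary = NULL) {
  if (bias_concentration < 0) stop("bias_concentration < 0")
  stopifnot(n_endpoints >= 1)
  mu <- bias_direction * pi / 180
  if (is.null(n_primary)) n_primary <- min(3, n_endpoints)
  with_seed(seed, {
    nodes <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                        radius = 5, parent = -1)
    nid <- 1
    grow <- function(parent_id, px, py) {
      th <- rvonmises(1, mu, bias_concentration)
      len <- if (is.finite(bias_concentration))
        segment_length * stats::runif(1, 0.5, 1.5) else segment_length
      nid <<- nid + 1
      nodes[nrow(nodes) + 1, ] <<- list(nid, 3, px + len * cos(th),
                                        py + len * sin(th), 0, 0.5,
                                        parent_id)
      nid
    }
    tips <- vapply(seq_len(n_primary), function(i) grow(1, 0, 0), 1)
    while (length(tips) < n_endpoints) {
      # branch a random tip into two daughters
      k <- sample.int(length(tips), 1)
      tip <- tips[k]
      row <- nodes[nodes$id == tip, ]
      d1 <- grow(tip, row$x, row$y)
      d2 <- grow(tip, row$x, row$y)
      tips <- c(tips[-k], d1, d2)
    }
    # extend each tip a couple more segments
    for (e in seq_len(2)) {
      tips <- vapply(tips, function(tip) {
        row <- nodes[nodes$id == tip, ]
        grow(tip, row$x, row$y)
      }, 1)
    }
    m <- morphology(nodes)
    ep <- nodes[nodes$id %in% endpoint_ids(m), ]
    attr(m, "planted_angles") <- (atan2(ep$y, ep$x) * 180 / pi) %% 360
    m
  })
}

#' Simulate a segmented-object field with planted colocalization
#'
#' Places `n_boutons` non-overlapping circular-polygon boutons in a
#' square field, then exactly `round(planted_coloc_fraction * n_puncta)`
#' puncta centres inside randomly chosen boutons and the remainder
#' strictly outside all boutons, so the planted puncta colocalization
#' fraction is recovered exactly by [colocalize_objects()].
#'
#' @param n_boutons,n_puncta Object counts (>= 1).
#' @param planted_coloc_fraction Fraction of puncta planted inside
#'   boutons, in `[0, 1]`.
#' @param seed Optional RNG seed (local to this call).
#' @param field_size Side of the square field (micrometres).
#' @param bouton_radius Range of bouton radii (micrometres).
#' @return An [object_field()]; `attr(, "planted_inside")` flags the
#'   planted puncta.
#' @export
simulate_object_field <- function(n_boutons = 30, n_puncta = 100,
                                  planted_coloc_fraction = 0.14,
                                  seed = NULL, field_size = 50,
                                  bouton_radius = c(0.5, 1.2)) {
  stopifnot(planted_coloc_fraction >= 0, planted_coloc_fraction <= 1,
            n_boutons >= 1, n_puncta >= 1)
  with_seed(seed, {
    centers <- matrix(NA_real_, n_boutons, 2)
    radii <- stats::runif(n_boutons, bouton_radius[1], bouton_radius[2])
    placed <- 0; tries <- 0
    while (placed < n_boutons) {
      tries <- tries + 1
      if (tries > 20000) stop("infeasible geometry (field too crowded)")
      cand <- stats::runif(2, max(radii), field_size - max(radii))
      if (placed == 0 ||
          all(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2)) >
              radii[placed + 1] + radii[seq_len(placed)] + 0.5)) {
        placed <- placed + 1
        centers[placed, ] <- cand
      }
    }
    boutons <- lapply(seq_len(n_boutons), function(i)
      circle_polygon(centers[i, ], radii[i], n = 24))
    n_in <- round(planted_coloc_fraction * n_puncta)
    pts <- matrix(NA_real_, n_puncta, 2)
    if (n_in > 0) {
      host <- sample.int(n_boutons, n_in, replace = TRUE)
      for (j in seq_len(n_in)) {
        r <- radii[host[j]] * 0.9 * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        pts[j, ] <- centers[host[j], ] + r * c(cos(th), sin(th))
      }
    }
    if (n_in < n_puncta) {
      for (j in seq(n_in + 1, n_puncta)) {
        repeat {
          cand <- stats::runif(2, 0, field_size)
          d <- sqrt((centers[, 1] - cand[1])^2 +
                      (centers[, 2] - cand[2])^2)
          if (all(d > radii + 0.2)) { pts[j, ] <- cand; break }
        }
      }
    }
    fld <- object_field(boutons, pts)
    attr(fld, "planted_inside") <- seq_len(n_puncta) <= n_in
    fld
  })
}
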