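# Neurite morphometrics in the slice plane: endpoint polar profiles
# with a von Mises kernel density, 2-D Sholl analysis, ventral-root
# projection classification, and object-based colocalization with a
# perisomatic band ROI.

node_xy <- function(morph) {
  n <- morph$nodes
  soma <- n[n$id == morph$soma_id, ]
  list(nodes = n, soma = c(soma$x, soma$y))
}

# Path length (along the tree) from the soma to each node id.
path_lengths <- function(morph) {
  n <- morph$nodes
  pos <- match(n$parent, n$id)
  seg <- sqrt((n$x - n$x[pos])^2 + (n$y - n$y[pos])^2 +
                (n$z - n$z[pos])^2)
  seg[is.na(seg)] <- 0
  pl <- numeric(nrow(n))
  for (i in seq_len(nrow(n)))       # parents precede children
    pl[i] <- if (is.na(pos[i])) 0 else pl[pos[i]] + seg[i]
  stats::setNames(pl, n$id)
}

#' Polar profile of neurite endpoints
#'
#' Endpoint angle is the planar angle of (endpoint - soma), 0 degrees
#' along +x, counterclockwise; endpoint distance is the path length
#' from soma to endpoint along the tree. Per 45-degree bin the mean
#' path length of the endpoints falling in it (0 for empty bins), plus
#' a von Mises kernel density of the endpoint angles on a 1-degree
#' grid, normalized to integrate to 1 over the circle.
#'
#' @param morph A [morphology()] with at least one non-soma endpoint.
#' @param bin_width Polar bin width (degrees, divides 360).
#' @param kde_concentration Von Mises kernel concentration (default 8,
#'   roughly a 23-degree bandwidth).
#' @param distance `"path"` (dendritic length, default) or
#'   `"euclidean"`.
#' @return Object of class `"polar_profile"`: `endpoint_angles`,
#'   `endpoint_distances`, `bin_edges`, `bin_mean_length`, `kde`
#'   (data frame `angle`, `density` per radian).
#' @export
endpoint_polar_profile <- function(morph, bin_width = 45,
                                   kde_concentration = 8,
                                   distance = c("path", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(inherits(morph, "morphology"), 360 %% bin_width == 0)
  xy <- node_xy(morph)
  ep <- endpoint_ids(morph)
  if (!length(ep)) stop("morphology has no endpoints")
  rows <- xy$nodes[match(ep, xy$nodes$id), ]
  dx <- rows$x - xy$soma[1]; dy <- rows$y - xy$soma[2]
  if (all(dx == 0 & dy == 0)) stop("degenerate morphology")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  dist <- if (distance == "path") unname(path_lengths(morph)[
    as.character(ep)]) else sqrt(dx^2 + dy^2)
  edges <- seq(0, 360, by = bin_width)
  bin <- findInterval(ang, edges, rightmost.closed = FALSE)
  bin_mean <- vapply(seq_len(length(edges) - 1), function(b) {
    v <- dist[bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  grid <- 0:359
  th <- grid * pi / 180
  k <- kde_concentration
  dens <- vapply(th, function(g)
    mean(exp(k * cos(g - ang * pi / 180))) /
      (2 * pi * besselI(k, 0)), numeric(1))
  structure(list(endpoint_angles = ang, endpoint_distances = dist,
                 bin_edges = edges, bin_mean_length = bin_mean,
                 kde = data.frame(angle = grid, density = dens)),
            class = "polar_profile")
}

#' @export
print.polar_profile <- function(x, ...) {
  mode <- x$kde$angle[which.max(x$kde$density)]
  cat(sprintf("<polar_profile> %d endpoints, KDE mode at %d deg\n",
              length(x$endpoint_angles), mode))
  invisible(x)
}

# Number of intersection points of segment (p1, p2) with the circle of
# radius r about c0 (exact quadratic).
segment_circle_crossings <- function(p1, p2, c0, r) {
  d <- p2 - p1
  f <- p1 - c0
  a <- sum(d * d)
  if (a == 0) return(0L)
  b <- 2 * sum(f * d)
  cc <- sum(f * f) - r * r
  disc <- b * b - 4 * a * cc
  if (disc < 0) return(0L)
  sq <- sqrt(disc)
  ts <- c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
  if (disc == 0) ts <- ts[1]
  sum(ts > 0 & ts <= 1)
}

#' Sholl analysis in the slice plane
#'
#' Counts crossings of tree segments with concentric circles about the
#' soma (2-D Euclidean). The critical value is the radius of maximum
#' intersections (smallest on ties); the ramification index is the
#' maximum intersection count divided by the number of primary
#' neurites leaving the soma.
#'
#' @param morph A [morphology()].
#' @param radius_step Circle spacing (micrometres).
#' @return Object of class `"sholl_profile"`: `radii`,
#'   `intersections`, `critical_value`, `ramification_index`,
#'   `n_primary`.
#' @export
sholl_profile <- function(morph, radius_step = 10) {
  stopifnot(inherits(morph, "morphology"), radius_step > 0)
  n <- morph$nodes
  xy <- node_xy(morph)
  pos <- match(n$parent, n$id)
  segs <- which(!is.na(pos))
  if (!length(segs)) stop("morphology has no segments")
  n_primary <- sum(n$parent == morph$soma_id)
  if (n_primary == 0) stop("zero primary neurites")
  p1 <- cbind(n$x[pos[segs]], n$y[pos[segs]])
  p2 <- cbind(n$x[segs], n$y[segs])
  dmax <- max(sqrt((n$x - xy$soma[1])^2 + (n$y - xy$soma[2])^2))
  radii <- seq(radius_step, ceiling(dmax / radius_step) * radius_step,
               by = radius_step)
  inter <- vapply(radii, function(r)
    sum(vapply(seq_len(nrow(p1)), function(s)
      segment_circle_crossings(p1[s, ], p2[s, ], xy$soma, r),
      integer(1))), numeric(1))
  cv <- radii[which.max(inter)]
  structure(list(radii = radii, intersections = inter,
                 critical_value = cv,
                 ramification_index = max(inter) / n_primary,
                 n_primary = n_primary),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf(paste0("<sholl_profile> max %d intersections at %g um ",
                     "(ramification index %.2f over %d primaries)\n"),
              max(x$intersections), x$critical_value,
              x$ramification_index, x$n_primary))
  invisible(x)
}

#' Classify a ventral-root-projecting (VRP) morphology
#'
#' A cell is VRP when at least one endpoint whose angle falls in the
#' ventral-root sector has a path length of at least `min_length`
#' (default: the 60th percentile of the cell's endpoint path lengths),
#' i.e. a long neurite directed toward the ventral root exit.
#'
#' @param profile A `"polar_profile"`.
#' @param sector Angular sector (degrees, `c(from, to)`).
#' @param min_length Absolute length threshold (micrometres); `NULL`
#'   uses the percentile rule.
#' @param percentile Percentile for the default threshold.
#' @return Logical.
#' @export
classify_vrp <- function(profile, sector = c(90, 135),
                         min_length = NULL, percentile = 0.6) {
  stopifnot(inherits(profile, "polar_profile"))
  if (is.null(min_length))
    min_length <- stats::quantile(profile$endpoint_distances,
                                  percentile, names = FALSE)
  sel <- profile$endpoint_angles >= sector[1] &
    profile$endpoint_angles <= sector[2]
  any(sel & profile$endpoint_distances >= min_length)
}

#' Perisomatic band region of interest
#'
#' The band extends from `r_out` outside the traced cell perimeter to
#' `r_in` inside it (defaults 2 and 1 micrometres, giving the 3-um
#' band used for perisomatic segmentation). Area is closed-form via
#' the Steiner formula for convex perimeters and by grid integration
#' otherwise; if the erosion annihilates the polygon (cell thinner
#' than 2 `r_in`) the band is the dilation minus the original polygon,
#' with a warning.
#'
#' @param perimeter Simple polygon (n x 2 matrix, micrometres).
#' @param r_out,r_in Outward / inward extents (micrometres).
#' @return Object of class `"band_roi"` with `polygon`, `r_out`,
#'   `r_in`, `area` and `eroded_empty`.
#' @export
perisomatic_band_roi <- function(perimeter, r_out = 2, r_in = 1) {
  p <- as_poly(perimeter)
  if (!polygon_is_simple(p)) stop("perimeter polygon self-intersects")
  a <- polygon_area(p)
  per <- polygon_perimeter(p)
  # does the erosion survive? test whether any interior point is
  # deeper than r_in
  depth <- -min(signed_dist_to_polygon(interior_probe_points(p), p))
  eroded_empty <- depth <= r_in
  r_in_eff <- if (eroded_empty) 0 else r_in
  if (eroded_empty)
    warning("erosion annihilates polygon; band = dilation minus original")
  if (polygon_is_convex(p)) {
    area_out <- a + per * r_out + pi * r_out^2
    area_in <- if (r_in_eff > 0) a - per * r_in_eff + pi * r_in_eff^2
               else a
    area <- area_out - area_in
  } else {
    area <- band_area_grid(p, r_out, r_in_eff)
  }
  structure(list(polygon = p, r_out = r_out, r_in = r_in_eff,
                 area = area, eroded_empty = eroded_empty),
            class = "band_roi")
}

interior_probe_points <- function(p, n = 400) {
  bb <- apply(p, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = ceiling(sqrt(n)))
  gy <- seq(bb[1, 2], bb[2, 2], length.out = ceiling(sqrt(n)))
  pts <- as.matrix(expand.grid(gx, gy))
  pts[points_in_polygon_raw(pts, p), , drop = FALSE]
}

band_area_grid <- function(p, r_out, r_in, h = NULL) {
  if (is.null(h)) h <- max(r_out, 0.5) / 40
  bb <- apply(p, 2, range)
  gx <- seq(bb[1, 1] - r_out - h, bb[2, 1] + r_out + h, by = h)
  gy <- seq(bb[1, 2] - r_out - h, bb[2, 2] + r_out + h, by = h)
  pts <- as.matrix(expand.grid(gx, gy))
  sd <- signed_dist_to_polygon(pts, p)
  sum(sd <= r_out & sd >= -r_in) * h * h
}

#' @export
print.band_roi <- function(x, ...) {
  cat(sprintf("<band_roi> %g um out / %g um in, area %.1f um^2%s\n",
              x$r_out, x$r_in, x$area,
              if (x$eroded_empty) " (erosion empty)" else ""))
  invisible(x)
}

#' Membership test for the perisomatic band
#'
#' @param band A `"band_roi"`.
#' @param pts n x 2 matrix of points.
#' @return Logical vector: inside the band (signed distance to the
#'   perimeter within `[-r_in, r_out]`).
#' @export
band_contains <- function(band, pts) {
  sd <- signed_dist_to_polygon(matrix(as.numeric(pts), ncol = 2),
                               band$polygon)
  sd <= band$r_out & sd >= -band$r_in
}

#' Object-based colocalization of puncta and boutons
#'
#' A punctum is colocalized when its centre lies inside (or on) a
#' bouton polygon; a bouton is colocalized when at least one punctum
#' centre lies inside it. With `band` given, only objects whose
#' centre/centroid falls in the perisomatic band enter the
#' denominators.
#'
#' @param field An [object_field()].
#' @param band Optional `"band_roi"` restricting the analysis.
#' @return List with `pct_boutons`, `pct_puncta`, `n_boutons`,
#'   `n_puncta`, and the per-object logical vectors
#'   `punctum_colocalized`, `bouton_colocalized`.
#' @export
colocalize_objects <- function(field, band = NULL) {
  stopifnot(inherits(field, "object_field"))
  boutons <- field$boutons
  puncta <- field$puncta
  if (!is.null(band)) {
    bc <- vapply(boutons, function(b) {
      cen <- colMeans(b)
      band_contains(band, matrix(cen, 1))
    }, logical(1))
    boutons <- boutons[bc]
    puncta <- puncta[band_contains(band, puncta), , drop = FALSE]
  }
  if (!length(boutons) || !nrow(puncta))
    stop("empty restricted object sets")
  hits <- matrix(FALSE, nrow(puncta), length(boutons))
  for (j in seq_along(boutons))
    hits[, j] <- points_in_polygon(puncta, boutons[[j]])
  p_col <- rowSums(hits) > 0
  b_col <- colSums(hits) > 0
  list(pct_boutons = 100 * mean(b_col), pct_puncta = 100 * mean(p_col),
       n_boutons = length(boutons), n_puncta = nrow(puncta),
       punctum_colocalized = p_col, bouton_colocalized = b_col)
}
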