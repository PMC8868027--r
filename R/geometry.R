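# Small planar-geometry primitives used by the object-colocalization
# and perisomatic-band analyses. Polygons are n x 2 matrices of
# vertices in order, implicitly closed.

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(p) {
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

polygon_is_convex <- function(p, tol = 1e-9) {
  n <- nrow(p)
  i <- seq_len(n); j <- c(i[-1], 1L); k <- c(j[-1], j[1])
  cr <- (p[j, 1] - p[i, 1]) * (p[k, 2] - p[j, 2]) -
        (p[j, 2] - p[i, 2]) * (p[k, 1] - p[j, 1])
  all(cr >= -tol) || all(cr <= tol)
}

segments_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r)
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  if (polygon_is_convex(p)) return(TRUE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_intersect(p[idx[i, 1], ], p[idx[i, 2], ],
                             p[idx[j, 1], ], p[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' Even-odd ray casting; points lying on an edge (within `tol`) count
#' as inside, matching the object-colocalization rule that a punctum
#' centre "coinciding with the area of a bouton" includes its boundary.
#'
#' @param pts n x 2 matrix of points.
#' @param poly Polygon as an m x 2 vertex matrix.
#' @param tol Distance tolerance for the on-boundary test.
#' @return Logical vector of length n.
#' @export
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(pts); m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | (dist_to_polygon_boundary(pts, poly) <= tol)
}

# Unsigned distance from each point to the polygon boundary (vectorized
# over points, loop over edges).
dist_to_polygon_boundary <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  dmin <- rep(Inf, nrow(pts))
  j <- m
  for (i in seq_len(m)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
    j <- i
  }
  dmin
}

# Signed distance: negative inside the polygon, positive outside.
signed_dist_to_polygon <- function(pts, poly) {
  d <- dist_to_polygon_boundary(pts, poly)
  raw_in <- points_in_polygon_raw(pts, poly)
  ifelse(raw_in, -d, d)
}

points_in_polygon_raw <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(nrow(pts))
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Regular-polygon approximation of a circle (for synthetic boutons).
circle_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
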