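# Planar geometry helpers for the synthetic-country generator.
# All coordinates are kilometres in [0, width] x [0, height].

# Shoelace area of a polygon given as an n x 2 vertex matrix (no repeat of
# the first vertex).
polygonArea <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of a convex polygon against the half-plane
# a*x + b*y <= d.
clipHalfPlane <- function(poly, a, b, d) {
  n <- nrow(poly)
  if (is.null(n) || n == 0L) return(poly)
  side <- a * poly[, 1L] + b * poly[, 2L] - d
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- side[i] <= 1e-12
    pj_in <- side[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, , drop = FALSE])
    if (xor(pi_in, pj_in)) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seeds[k, ] within the rectangle [0,w] x [0,h]: clip the
# rectangle against the perpendicular-bisector half-plane towards every
# other seed. O(n) clips per cell; exact areas via the shoelace formula.
voronoiCell <- function(seeds, k, width, height) {
  poly <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  sk <- seeds[k, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == k) next
    sj <- seeds[j, ]
    a <- sj[1L] - sk[1L]
    b <- sj[2L] - sk[2L]
    d <- (sum(sj^2) - sum(sk^2)) / 2
    poly <- clipHalfPlane(poly, a, b, d)
    if (nrow(poly) < 3L) break
  }
  poly
}

# Index of the nearest seed for each query point; ties broken by lowest
# row index (hence lowest region_id for id-sorted seeds).
nearestSeed <- function(px, py, seeds) {
  d2 <- outer(px, seeds[, 1L], "-")^2 + outer(py, seeds[, 2L], "-")^2
  apply(d2, 1L, which.min)
}

# Great-circle distance in km between lon/lat degree points (haversine).
haversineKm <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
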