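# Polyline helpers. A polyline is an ordered n x 3 matrix of points; the
# pelvic brim and the obturator foramen rim are represented this way
# (closed rims repeat their first point).

as_polyline <- function(x, what = "polyline") {
  x <- as_point_matrix(x, what)
  if (nrow(x) < 2L) {
    stop_quadzone("quadzone_invalid_argument",
                  sprintf("%s needs at least 2 points", what))
  }
  x
}

# Resample so consecutive points are at most `step` apart (original
# vertices are kept; segments are subdivided uniformly).
densify_polyline <- function(poly, step) {
  segs <- diff(poly)
  lens <- sqrt(rowSums(segs^2))
  out <- vector("list", nrow(poly) - 1L)
  for (i in seq_len(nrow(poly) - 1L)) {
    n <- max(1L, ceiling(lens[i] / step))
    s <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- matrix(poly[i, ], nrow = n, ncol = 3L, byrow = TRUE) +
      outer(s, poly[i + 1L, ] - poly[i, ])
  }
  rbind(do.call(rbind, out), poly[nrow(poly), , drop = FALSE])
}

# Closest point on a polyline to each query point (exact per-segment
# projection, not sample-based). Returns list(points, dist, seg, tloc).
closest_on_polyline <- function(poly, queries) {
  queries <- as_point_matrix(queries)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  n <- nrow(queries)
  best <- rep(Inf, n)
  bp <- matrix(0, n, 3L)
  bseg <- integer(n)
  btl <- numeric(n)
  for (s in seq_len(nrow(a))) {
    ap <- queries - matrix(a[s, ], n, 3L, byrow = TRUE)
    t <- pmin(1, pmax(0, (ap %*% ab[s, ])[, 1L] / len2[s]))
    proj <- matrix(a[s, ], n, 3L, byrow = TRUE) + outer(t, ab[s, ])
    d2 <- rowSums((queries - proj)^2)
    sel <- d2 < best
    if (any(sel)) {
      best[sel] <- d2[sel]
      bp[sel, ] <- proj[sel, , drop = FALSE]
      bseg[sel] <- s
      btl[sel] <- t[sel]
    }
  }
  list(points = bp, dist = sqrt(best), seg = bseg, tloc = btl)
}

distance_to_polyline <- function(poly, queries) {
  closest_on_polyline(poly, queries)$dist
}

# Unit tangent of the polyline at the point nearest to `point`.
polyline_tangent_near <- function(poly, point) {
  cl <- closest_on_polyline(poly, matrix(point, ncol = 3L))
  s <- cl$seg[1L]
  tan <- poly[s + 1L, ] - poly[s, ]
  tan / sqrt(sum(tan^2))
}
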