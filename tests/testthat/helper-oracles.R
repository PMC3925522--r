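# Independent geometric oracles, deliberately implemented with different
# algorithms than the package kernels.

# Ray-triangle intersection by solving the 3x3 barycentric system
# o + t d = a + u (b - a) + v (c - a) directly.
oracle_ray_tri <- function(o, d, a, b, c) {
  M <- cbind(-d, b - a, c - a)
  if (abs(det(M)) < 1e-14) return(NA_real_)
  s <- solve(M, o - a)
  t <- s[1L]
  u <- s[2L]
  v <- s[3L]
  if (u < -1e-12 || v < -1e-12 || u + v > 1 + 1e-12) return(NA_real_)
  t
}

# All hits of one ray against a mesh, sorted; pure R.
oracle_ray_hits <- function(mesh, o, d, eps = 1e-6, max_t = Inf) {
  ts <- vapply(seq_len(nrow(mesh$faces)), function(f) {
    idx <- mesh$faces[f, ]
    t <- oracle_ray_tri(o, d, mesh$vertices[idx[1L], ],
                        mesh$vertices[idx[2L], ], mesh$vertices[idx[3L], ])
    if (is.na(t) || t <= eps || t > max_t) NA_real_ else t
  }, numeric(1L))
  sort(ts[!is.na(ts)])
}

# Open-segment occlusion test, pure R (brute force per triangle).
oracle_segment_occluded <- function(mesh, viewpoint, points, eps = 1e-6) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- points[i, ] - viewpoint
    L <- sqrt(sum(d^2))
    for (f in seq_len(nrow(mesh$faces))) {
      idx <- mesh$faces[f, ]
      t <- oracle_ray_tri(viewpoint, d, mesh$vertices[idx[1L], ],
                          mesh$vertices[idx[2L], ], mesh$vertices[idx[3L], ])
      if (!is.na(t) && t > eps / L && t < 1 - eps / L) return(TRUE)
    }
    FALSE
  }, logical(1L))
}

# Point-triangle distance assembled from point-plane and point-segment
# distances (no region-walk logic shared with the C++ kernel).
oracle_point_tri_dist <- function(p, a, b, c) {
  seg_dist <- function(p, x, y) {
    d <- y - x
    t <- sum((p - x) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((p - (x + t * d))^2))
  }
  n <- pracma_cross(b - a, c - a)
  nl <- sqrt(sum(n^2))
  best <- min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
  if (nl > 1e-14) {
    n <- n / nl
    q <- p - sum((p - a) * n) * n
    # inside test via barycentric coordinates of the projection
    M <- cbind(b - a, c - a)
    uv <- qr.solve(M, q - a)
    if (uv[1L] >= 0 && uv[2L] >= 0 && sum(uv) <= 1) {
      best <- min(best, abs(sum((p - a) * n)))
    }
  }
  best
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

oracle_mesh_distance <- function(mesh, p) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f) {
    idx <- mesh$faces[f, ]
    oracle_point_tri_dist(p, mesh$vertices[idx[1L], ],
                          mesh$vertices[idx[2L], ], mesh$vertices[idx[3L], ])
  }, numeric(1L)))
}

# Exact occlusion of the segment viewpoint -> p by a sphere.
oracle_sphere_occluded <- function(points, viewpoint, center, radius) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- points[i, ] - viewpoint
    tt <- sum((center - viewpoint) * d) / sum(d * d)
    tt <- min(1, max(0, tt))
    sqrt(sum((viewpoint + tt * d - center)^2)) <= radius
  }, logical(1L))
}

# Distance from the infinite line through v and p to the sphere centre
# (for boundary-band exclusion in shadow comparisons).
oracle_segment_sphere_margin <- function(points, viewpoint, center, radius) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- points[i, ] - viewpoint
    tt <- sum((center - viewpoint) * d) / sum(d * d)
    tt <- min(1, max(0, tt))
    abs(sqrt(sum((viewpoint + tt * d - center)^2)) - radius)
  }, numeric(1L))
}

# Lat-long sphere triangulation (different construction from the package
# cap generator).
sphere_mesh <- function(center = c(0, 0, 0), radius = 10, n_lat = 16L,
                        n_lon = 24L) {
  lat <- seq(0, pi, length.out = n_lat + 1L)
  verts <- list(center + c(0, 0, radius))
  for (i in seq_len(n_lat - 1L)) {
    phi <- lat[i + 1L]
    th <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
    verts[[i + 1L]] <- cbind(center[1L] + radius * sin(phi) * cos(th),
                             center[2L] + radius * sin(phi) * sin(th),
                             center[3L] + radius * cos(phi))
  }
  verts[[n_lat + 1L]] <- matrix(center + c(0, 0, -radius), ncol = 3L)
  V <- do.call(rbind, verts)
  faces <- list()
  # top fan
  faces[[1L]] <- cbind(1L, 1L + seq_len(n_lon),
                       1L + c(seq_len(n_lon - 1L) + 1L, 1L))
  for (i in seq_len(n_lat - 2L)) {
    i0 <- 1L + (i - 1L) * n_lon
    i1 <- i0 + n_lon
    jj <- c(seq_len(n_lon - 1L) + 1L, 1L)
    faces[[i + 1L]] <- rbind(cbind(i0 + seq_len(n_lon), i0 + jj, i1 + jj),
                             cbind(i0 + seq_len(n_lon), i1 + jj,
                                   i1 + seq_len(n_lon)))
  }
  bot <- nrow(V)
  i0 <- 1L + (n_lat - 2L) * n_lon
  jj <- c(seq_len(n_lon - 1L) + 1L, 1L)
  faces[[n_lat]] <- cbind(bot, i0 + jj, i0 + seq_len(n_lon))
  triangle_mesh(V, do.call(rbind, faces), name = "oracle_sphere")
}

# Unit tetrahedron used by the I/O round-trip tests.
tetra_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L),
                      c(2L, 3L, 4L)),
                name = "tetra")
}

# Shared default-phantom pipeline run (used by several acceptance checks).
default_run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(default_run_cache$run)) {
    sp <- phantom_spec()
    ph <- generate_phantom(sp)
    default_run_cache$spec <- sp
    default_run_cache$truth <- analytic_truth(sp)
    default_run_cache$run <- run_subject(ph, quadzone_config())
  }
  list(spec = default_run_cache$spec, truth = default_run_cache$truth,
       run = default_run_cache$run)
}
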