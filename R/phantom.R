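# Parametric hemipelvis phantom with analytic ground truth.
#
# Local phantom coordinates (canonical left side, mm): the quadrilateral
# plate occupies the plane z = 0; x runs toward the anterior/pubic side,
# y toward the head (proximal), z medially toward the surgeon. The
# acetabular cup is a spherical cap buried below the plate (its centre of
# curvature at z < 0, the articular dome just under the plate), the pelvic
# brim is a gently curved arc running obliquely above the cup from the
# superomedial to the inferolateral corner, and the obturator foramen is
# an elliptic hole inferolateral of the cup. The simulated Stoppa incision
# is a longitudinal segment anterior and medial of the plate.

#' Parametric phantom specification
#'
#' All lengths in mm; every linear dimension is multiplied by `scale`.
#' The defaults describe a plausible adult hemipelvis (acetabular radius
#' 24 mm, plate roughly 64 x 68 mm, 90 mm incision); none of them is a
#' population value, they exist to give every pipeline stage a known
#' ground truth.
#'
#' @param acetabulum_radius radius of the spherical articular cup (mm).
#' @param cup_clearance distance from the plate plane to the articular
#'   sphere (the bone stock between the quadrilateral surface and the
#'   joint, mm); the cup centre sits at depth `-(radius + clearance)`.
#' @param cup_center_xy in-plane position of the cup centre.
#' @param cup_half_angle_deg angular extent of the articular cap around
#'   its axis (degrees); the axis points medially (+z).
#' @param plate_x,plate_y plate extents (mm).
#' @param plate_thickness slab thickness (mm).
#' @param brim_anchors 3 x 2 matrix of in-plane points the brim arc passes
#'   through (superomedial, mid, inferolateral).
#' @param foramen_center,foramen_axes obturator foramen ellipse (in-plane
#'   centre and semi-axes, mm).
#' @param canal_angle_deg position of the obturator canal point on the
#'   foramen rim, measured from the rim top toward +x; the default places
#'   it superolaterally, where the obturator bundle enters.
#' @param incision_proximal,incision_distal simulated incision endpoints
#'   (mm, above the plate).
#' @param mesh_resolution target mesh edge length (mm).
#' @param entry_spacing spacing of the candidate entry-point grid (mm).
#' @param scale global scale factor.
#' @param noise_sigma vertex jitter (mm); analytic truth requires 0.
#' @param lumpy,lump_amplitude radial low-frequency perturbation of the
#'   cup ("the acetabulum is not an accurate hemisphere"); disables the
#'   analytic truth, brute-force oracles still apply.
#' @param seed integer seed for the stochastic options.
#' @return a validated `phantom_spec`.
#' @export
phantom_spec <- function(acetabulum_radius = 24,
                         cup_clearance = 2,
                         cup_center_xy = c(0, 0),
                         cup_half_angle_deg = 60,
                         plate_x = c(-32, 32),
                         plate_y = c(-38, 30),
                         plate_thickness = 4,
                         brim_anchors = rbind(c(-32, 22.5),
                                              c(2.75, 4.76),
                                              c(44, -20.5)),
                         foramen_center = c(18, -20),
                         foramen_axes = c(11, 12),
                         canal_angle_deg = 65,
                         incision_proximal = c(40, 45, 20),
                         incision_distal = c(40, -45, 20),
                         mesh_resolution = 1.5,
                         entry_spacing = 1.25,
                         scale = 1,
                         noise_sigma = 0,
                         lumpy = FALSE,
                         lump_amplitude = 0.5,
                         seed = 42L) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop_quadzone("quadzone_spec_error", "scale must be positive")
  }
  s <- scale
  spec <- list(
    acetabulum_radius = acetabulum_radius * s,
    cup_clearance = cup_clearance * s,
    cup_center_xy = as.numeric(cup_center_xy) * s,
    cup_half_angle_deg = cup_half_angle_deg,
    plate_x = as.numeric(plate_x) * s,
    plate_y = as.numeric(plate_y) * s,
    plate_thickness = plate_thickness * s,
    brim_anchors = as.matrix(brim_anchors) * s,
    foramen_center = as.numeric(foramen_center) * s,
    foramen_axes = as.numeric(foramen_axes) * s,
    canal_angle_deg = canal_angle_deg,
    incision_proximal = as.numeric(incision_proximal) * s,
    incision_distal = as.numeric(incision_distal) * s,
    mesh_resolution = mesh_resolution * s,
    entry_spacing = entry_spacing * s,
    scale = s,
    noise_sigma = noise_sigma * s,
    lumpy = isTRUE(lumpy),
    lump_amplitude = lump_amplitude * s,
    seed = as.integer(seed)
  )
  spec <- compute_phantom_derived(spec)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

compute_phantom_derived <- function(spec) {
  spec$acetabulum_center <- c(spec$cup_center_xy,
                              -(spec$acetabulum_radius + spec$cup_clearance))
  cc <- circumcircle2(spec$brim_anchors)
  spec$brim_center <- cc$center
  spec$brim_radius <- cc$radius
  ang <- function(p) atan2(p[1L] - cc$center[1L], p[2L] - cc$center[2L])
  spec$brim_span <- sort(c(ang(spec$brim_anchors[1L, ]),
                           ang(spec$brim_anchors[3L, ])))
  spec$foramen_top <- c(spec$foramen_center[1L],
                        spec$foramen_center[2L] + spec$foramen_axes[2L], 0)
  ca <- spec$canal_angle_deg * pi / 180
  spec$obturator_canal <- c(
    spec$foramen_center[1L] + spec$foramen_axes[1L] * sin(ca),
    spec$foramen_center[2L] + spec$foramen_axes[2L] * cos(ca), 0)
  spec
}

circumcircle2 <- function(anchors) {
  A <- anchors[1L, ]
  B <- anchors[2L, ]
  C <- anchors[3L, ]
  D <- 2 * (A[1L] * (B[2L] - C[2L]) + B[1L] * (C[2L] - A[2L]) +
            C[1L] * (A[2L] - B[2L]))
  if (abs(D) < 1e-9) {
    stop_quadzone("quadzone_spec_error", "brim anchors are collinear")
  }
  ux <- (sum(A^2) * (B[2L] - C[2L]) + sum(B^2) * (C[2L] - A[2L]) +
         sum(C^2) * (A[2L] - B[2L])) / D
  uy <- (sum(A^2) * (C[1L] - B[1L]) + sum(B^2) * (A[1L] - C[1L]) +
         sum(C^2) * (B[1L] - A[1L])) / D
  center <- c(ux, uy)
  list(center = center, radius = sqrt(sum((A - center)^2)))
}

validate_phantom_spec <- function(spec) {
  if (spec$acetabulum_radius <= 0) {
    stop_quadzone("quadzone_spec_error", "acetabulum_radius must be positive")
  }
  if (spec$cup_clearance <= 0 ||
      spec$cup_clearance >= spec$acetabulum_radius / 4) {
    stop_quadzone("quadzone_spec_error",
                  "cup_clearance must be positive and small relative to the cup radius (cup adjacent to the plate)")
  }
  if (spec$cup_half_angle_deg <= 30 || spec$cup_half_angle_deg > 90) {
    stop_quadzone("quadzone_spec_error",
                  "cup_half_angle_deg must be in (30, 90]")
  }
  fx <- spec$foramen_center[1L] + c(-1, 1) * spec$foramen_axes[1L]
  fy <- spec$foramen_center[2L] + c(-1, 1) * spec$foramen_axes[2L]
  m <- spec$scale
  if (fx[1L] <= spec$plate_x[1L] + m || fx[2L] >= spec$plate_x[2L] - m ||
      fy[1L] <= spec$plate_y[1L] + m || fy[2L] >= spec$plate_y[2L] - m) {
    stop_quadzone("quadzone_spec_error",
                  "obturator foramen must lie strictly inside the plate")
  }
  if (any(spec$foramen_axes <= 0)) {
    stop_quadzone("quadzone_spec_error", "foramen axes must be positive")
  }
  # cup must not interpenetrate the plate
  cl <- pmin(pmax(spec$cup_center_xy, c(spec$plate_x[1L], spec$plate_y[1L])),
             c(spec$plate_x[2L], spec$plate_y[2L]))
  dmin <- sqrt(sum((cl - spec$cup_center_xy)^2) +
               spec$acetabulum_center[3L]^2)
  if (dmin <= spec$acetabulum_radius) {
    stop_quadzone("quadzone_spec_error",
                  "articular sphere interpenetrates the plate")
  }
  if (spec$incision_proximal[3L] <= 0 || spec$incision_distal[3L] <= 0) {
    stop_quadzone("quadzone_spec_error",
                  "incision endpoints must lie above the plate plane")
  }
  # the foramen must sit on the analysed (cup) side of the brim
  if (!brim_same_side(spec, rbind(spec$foramen_center, spec$cup_center_xy))[1L]) {
    stop_quadzone("quadzone_spec_error",
                  "foramen must lie on the quadrilateral side of the brim")
  }
  if (spec$mesh_resolution <= 0 || spec$entry_spacing <= 0) {
    stop_quadzone("quadzone_spec_error",
                  "mesh_resolution and entry_spacing must be positive")
  }
  invisible(spec)
}

brim_same_side <- function(spec, p2) {
  # TRUE for points on the same side of the brim circle as the cup centre
  ref_out <- sqrt(sum((spec$cup_center_xy - spec$brim_center)^2)) >
    spec$brim_radius
  d <- sqrt((p2[, 1L] - spec$brim_center[1L])^2 +
            (p2[, 2L] - spec$brim_center[2L])^2)
  (d > spec$brim_radius) == ref_out
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec: cup r=%.1f mm at depth %.1f, plate %.0fx%.0f mm, scale %.2f%s>\n",
    x$acetabulum_radius, -x$acetabulum_center[3L],
    diff(x$plate_x), diff(x$plate_y), x$scale,
    if (x$lumpy) ", lumpy cup" else ""))
  invisible(x)
}

# In-plane membership test for the quadrilateral analysis region: on the
# plate, on the cup side of the brim, outside the foramen.
phantom_region_filter <- function(spec) {
  force(spec)
  function(points) {
    points <- as_point_matrix(points)
    p2 <- points[, 1:2, drop = FALSE]
    on_plate <- abs(points[, 3L]) <= 0.5 * spec$scale &
      p2[, 1L] >= spec$plate_x[1L] & p2[, 1L] <= spec$plate_x[2L] &
      p2[, 2L] >= spec$plate_y[1L] & p2[, 2L] <= spec$plate_y[2L]
    ell <- ((p2[, 1L] - spec$foramen_center[1L]) / spec$foramen_axes[1L])^2 +
      ((p2[, 2L] - spec$foramen_center[2L]) / spec$foramen_axes[2L])^2
    on_plate & ell >= 1.04 & brim_same_side(spec, p2)
  }
}

brim_point_at <- function(spec, theta) {
  cbind(spec$brim_center[1L] + spec$brim_radius * sin(theta),
        spec$brim_center[2L] + spec$brim_radius * cos(theta), 0)
}

#' Generate a phantom subject
#'
#' Builds the watertight inner-surface slab (quadrilateral plate with the
#' obturator foramen as a through-hole), the open acetabular articular cap,
#' the landmark set (brim and foramen rim polylines sampled at 0.5 mm,
#' canal and foramen-top points, incision endpoints) and the candidate
#' entry-point grid. Generation is deterministic: the same spec and seed
#' give identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_subject` list: `inner_surface` and `acetabular_cap`
#'   meshes, `landmarks`, `entry_points`, `region_filter`, and the spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- make_lcg(spec$seed)
  slab <- build_plate_slab(spec, rng)
  cap <- build_articular_cap(spec, rng)
  step <- min(0.5 * spec$scale, 0.5)
  th <- seq(spec$brim_span[1L], spec$brim_span[2L],
            length.out = max(64L, ceiling(spec$brim_radius *
              diff(spec$brim_span) / step)) + 1L)
  brim <- brim_point_at(spec, th)
  phi <- seq(0, 2 * pi, length.out = max(64L,
    ceiling(2 * pi * max(spec$foramen_axes) / step)) + 1L)
  rim <- cbind(spec$foramen_center[1L] + spec$foramen_axes[1L] * sin(phi),
               spec$foramen_center[2L] + spec$foramen_axes[2L] * cos(phi), 0)
  entry <- build_entry_grid(spec)
  structure(list(
    inner_surface = slab,
    acetabular_cap = cap,
    landmarks = list(brim = brim,
                     foramen_rim = rim,
                     obturator_canal = spec$obturator_canal,
                     foramen_top = spec$foramen_top,
                     incision = list(proximal = spec$incision_proximal,
                                     distal = spec$incision_distal)),
    entry_points = entry,
    region_filter = phantom_region_filter(spec),
    spec = spec
  ), class = "phantom_subject")
}

# Minimal deterministic generator (Lehmer LCG) so phantom randomness never
# touches R's global RNG stream.
make_lcg <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

build_entry_grid <- function(spec) {
  h <- spec$entry_spacing
  xs <- seq(spec$plate_x[1L], spec$plate_x[2L], by = h)
  ys <- seq(spec$plate_y[1L], spec$plate_y[2L], by = h)
  g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), 0)
  g[phantom_region_filter(spec)(g), , drop = FALSE]
}

# Watertight slab with an elliptic through-hole: the region between the
# foramen rim and the plate boundary is triangulated as radial bands
# (the rectangle is star-shaped about the foramen centre), mirrored to
# the bottom face and closed by the outer and inner walls.
build_plate_slab <- function(spec, rng) {
  res <- spec$mesh_resolution
  fc <- spec$foramen_center
  a <- spec$foramen_axes[1L]
  b <- spec$foramen_axes[2L]
  per <- 2 * pi * sqrt((a^2 + b^2) / 2)
  nth <- max(24L, ceiling(per / res))
  phi <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  inner <- cbind(fc[1L] + a * sin(phi), fc[2L] + b * cos(phi))
  outer <- t(vapply(phi, function(p) ray_to_rect(fc, c(sin(p), cos(p)),
                                                 spec$plate_x, spec$plate_y),
                    numeric(2L)))
  gap <- max(sqrt(rowSums((outer - inner)^2)))
  nr <- max(2L, ceiling(gap / res))
  nz <- max(1L, ceiling(spec$plate_thickness / res))
  rings <- lapply(0:nr, function(j) {
    s <- j / nr
    inner + s * (outer - inner)
  })
  noise <- if (spec$noise_sigma > 0) spec$noise_sigma else 0

  verts <- list()
  faces <- list()
  nv <- 0L
  add_ring_sheet <- function(rings2, z, flip = FALSE) {
    # rings2: list of (nth x 2); returns face block, appends vertices
    base <- nv
    for (r in rings2) {
      verts[[length(verts) + 1L]] <<- cbind(r, z)
    }
    nv <<- nv + length(rings2) * nth
    f <- list()
    for (j in seq_len(length(rings2) - 1L)) {
      i0 <- base + (j - 1L) * nth
      i1 <- base + j * nth
      ii <- seq_len(nth)
      jj <- c(seq_len(nth - 1L) + 1L, 1L)
      q1 <- cbind(i0 + ii, i0 + jj, i1 + jj)
      q2 <- cbind(i0 + ii, i1 + jj, i1 + ii)
      f[[j]] <- rbind(q1, q2)
    }
    f <- do.call(rbind, f)
    if (flip) f <- f[, c(1L, 3L, 2L)]
    faces[[length(faces) + 1L]] <<- f
  }
  add_ring_sheet(rings, 0)
  add_ring_sheet(rings, -spec$plate_thickness, flip = TRUE)
  # walls: stack of loops from z=0 to z=-thickness for outer boundary and
  # foramen wall
  zlevels <- seq(0, -spec$plate_thickness, length.out = nz + 1L)
  add_wall <- function(loop2, flip) {
    lev <- lapply(zlevels, function(z) loop2)
    base <- nv
    for (k in seq_along(zlevels)) {
      verts[[length(verts) + 1L]] <<- cbind(loop2, zlevels[k])
    }
    nv <<- nv + length(zlevels) * nth
    f <- list()
    for (j in seq_len(nz)) {
      i0 <- base + (j - 1L) * nth
      i1 <- base + j * nth
      ii <- seq_len(nth)
      jj <- c(seq_len(nth - 1L) + 1L, 1L)
      f[[j]] <- rbind(cbind(i0 + ii, i0 + jj, i1 + jj),
                      cbind(i0 + ii, i1 + jj, i1 + ii))
    }
    f <- do.call(rbind, f)
    if (flip) f <- f[, c(1L, 3L, 2L)]
    faces[[length(faces) + 1L]] <<- f
  }
  add_wall(outer, flip = FALSE)
  add_wall(inner, flip = TRUE)
  V <- do.call(rbind, verts)
  if (noise > 0) {
    V[, 3L] <- V[, 3L] + noise * (rng(nrow(V)) - 0.5) * 2
  }
  triangle_mesh(V, do.call(rbind, faces), name = "phantom_inner_surface")
}

ray_to_rect <- function(origin, dirv, xr, yr) {
  tx <- if (dirv[1L] > 1e-12) (xr[2L] - origin[1L]) / dirv[1L] else
    if (dirv[1L] < -1e-12) (xr[1L] - origin[1L]) / dirv[1L] else Inf
  ty <- if (dirv[2L] > 1e-12) (yr[2L] - origin[2L]) / dirv[2L] else
    if (dirv[2L] < -1e-12) (yr[1L] - origin[2L]) / dirv[2L] else Inf
  origin + min(tx, ty) * dirv
}

# Spherical cap around the cup axis (+z, medial): polar rings from the
# apex, the articular dome facing the plate.
build_articular_cap <- function(spec, rng) {
  r <- spec$acetabulum_radius
  c3 <- spec$acetabulum_center
  half <- spec$cup_half_angle_deg * pi / 180
  res <- spec$mesh_resolution
  nphi <- max(6L, ceiling(r * half / res))
  phis <- seq(0, half, length.out = nphi + 1L)
  lump <- if (spec$lumpy) {
    ph <- rng(2) * 2 * pi
    function(theta, phi) {
      1 + (spec$lump_amplitude / r) * sin(3 * theta + ph[1L]) *
        sin(2 * phi + ph[2L])
    }
  } else {
    function(theta, phi) 1
  }
  verts <- list(matrix(c3 + c(0, 0, r * lump(0, 0)), ncol = 3L))
  ring_start <- integer(nphi)
  ring_n <- integer(nphi)
  nv <- 1L
  for (k in seq_len(nphi)) {
    phi <- phis[k + 1L]
    m <- max(6L, ceiling(2 * pi * r * sin(phi) / res))
    th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    rr <- r * vapply(th, function(t) lump(t, phi), numeric(1L))
    verts[[k + 1L]] <- cbind(c3[1L] + rr * sin(phi) * cos(th),
                             c3[2L] + rr * sin(phi) * sin(th),
                             c3[3L] + rr * cos(phi))
    ring_start[k] <- nv
    ring_n[k] <- m
    nv <- nv + m
  }
  faces <- list()
  # apex fan
  m1 <- ring_n[1L]
  faces[[1L]] <- cbind(1L, 1L + seq_len(m1), 1L + c(seq_len(m1 - 1L) + 1L, 1L))
  # ring-to-ring strips (rings can have different counts; connect by
  # nearest angular neighbour)
  for (k in seq_len(nphi - 1L)) {
    i0 <- ring_start[k] + 1L
    n0 <- ring_n[k]
    i1 <- ring_start[k + 1L] + 1L
    n1 <- ring_n[k + 1L]
    f <- stitch_rings(i0, n0, i1, n1)
    faces[[k + 1L]] <- f
  }
  V <- do.call(rbind, verts)
  if (spec$noise_sigma > 0) {
    rad <- V - matrix(c3, nrow(V), 3L, byrow = TRUE)
    rl <- sqrt(rowSums(rad^2))
    V <- V + rad / rl * (spec$noise_sigma * (rng(nrow(V)) - 0.5) * 2)
  }
  triangle_mesh(V, do.call(rbind, faces), name = "phantom_acetabular_cap")
}

# Triangulate between two closed rings of sizes n0 and n1 (1-based global
# start indices i0, i1) by marching the smaller angular gap.
stitch_rings <- function(i0, n0, i1, n1) {
  f <- matrix(0L, n0 + n1, 3L)
  a <- 0L
  b <- 0L
  k <- 0L
  while (a < n0 || b < n1) {
    ta <- (a + 1) / n0
    tb <- (b + 1) / n1
    k <- k + 1L
    if (b >= n1 || (a < n0 && ta <= tb)) {
      f[k, ] <- c(i0 + a %% n0, i0 + (a + 1L) %% n0, i1 + b %% n1)
      a <- a + 1L
    } else {
      f[k, ] <- c(i0 + a %% n0, i1 + (b + 1L) %% n1, i1 + b %% n1)
      b <- b + 1L
    }
  }
  f[seq_len(k), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Analytic ground truth

# Exact occlusion of the open segment viewpoint -> p by the offset sphere
# of radius r + d around the cup centre. Valid because every tangency and
# footprint contact of an admissible sight line lies on the articular cap
# (the cap generously covers the plate-facing side of the sphere).
truth_occluded <- function(points, viewpoint, center, radius) {
  points <- as_point_matrix(points)
  d <- points - matrix(viewpoint, nrow(points), 3L, byrow = TRUE)
  cv <- matrix(center - viewpoint, nrow(points), 3L, byrow = TRUE)
  tt <- pmin(1, pmax(0, rowSums(d * cv) / rowSums(d * d)))
  cp <- matrix(viewpoint, nrow(points), 3L, byrow = TRUE) + d * tt
  sqrt(rowSums((cp - matrix(center, nrow(points), 3L, byrow = TRUE))^2)) <=
    radius
}

truth_danger_pred <- function(spec, R, viewpoints) {
  function(points) {
    points <- as_point_matrix(points)
    out <- rep(TRUE, nrow(points))
    for (i in seq_len(nrow(viewpoints))) {
      act <- which(out)
      if (!length(act)) break
      out[act] <- truth_occluded(points[act, , drop = FALSE],
                                 viewpoints[i, ], spec$acetabulum_center, R)
    }
    out
  }
}

# Conic coefficients (a, b, c, d, e, f) of the shadow boundary of the
# offset sphere on the plate plane z = 0, from the tangent-cone quadric:
# a x^2 + b x y + c y^2 + d x + e y + f = 0.
shadow_conic <- function(viewpoint, center, radius) {
  u <- center - viewpoint
  k2 <- sum(u^2) - radius^2
  A <- outer(u, u) - k2 * diag(3L)
  v <- viewpoint
  a <- A[1L, 1L]
  b <- 2 * A[1L, 2L]
  cc <- A[2L, 2L]
  d <- -2 * A[1L, 1L] * v[1L] - 2 * A[1L, 2L] * v[2L] - 2 * A[1L, 3L] * v[3L]
  e <- -2 * A[2L, 2L] * v[2L] - 2 * A[1L, 2L] * v[1L] - 2 * A[2L, 3L] * v[3L]
  f <- A[1L, 1L] * v[1L]^2 + A[2L, 2L] * v[2L]^2 + A[3L, 3L] * v[3L]^2 +
    2 * A[1L, 2L] * v[1L] * v[2L] + 2 * A[1L, 3L] * v[1L] * v[3L] +
    2 * A[2L, 3L] * v[2L] * v[3L]
  c(a = a, b = b, c = cc, d = d, e = e, f = f)
}

truth_brim_boundary <- function(spec, R, viewpoint, pick) {
  th <- seq(spec$brim_span[1L], spec$brim_span[2L], length.out = 4000L)
  occ <- truth_occluded(brim_point_at(spec, th), viewpoint,
                        spec$acetabulum_center, R)
  if (all(occ)) {
    stop_quadzone("quadzone_no_landmarks", "entire brim occluded (truth)")
  }
  if (!any(occ)) {
    stop_quadzone("quadzone_no_landmarks", "brim never occluded (truth)")
  }
  flips <- which(diff(occ) != 0L)
  bts <- vapply(flips, function(i) {
    a <- th[i]
    b <- th[i + 1L]
    fa <- occ[i]
    for (it in 1:60) {
      mid <- (a + b) / 2
      if (truth_occluded(brim_point_at(spec, mid), viewpoint,
                         spec$acetabulum_center, R) == fa) a <- mid else b <- mid
    }
    (a + b) / 2
  }, numeric(1L))
  pts <- brim_point_at(spec, bts)
  dc <- sqrt(rowSums((pts - matrix(spec$obturator_canal, nrow(pts), 3L,
                                   byrow = TRUE))^2))
  pts[if (pick == "nearest") which.min(dc) else which.max(dc), ]
}

# Coarse feasible seed for the truth extremal searches.
truth_danger_seed <- function(spec, R, viewpoints, objective) {
  region <- phantom_region_filter(spec)
  pred <- truth_danger_pred(spec, R, viewpoints)
  h <- 0.4 * spec$scale
  xs <- seq(spec$plate_x[1L], spec$plate_x[2L], by = h)
  ys <- seq(spec$plate_y[1L], spec$plate_y[2L], by = h)
  g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), 0)
  g <- g[region(g), , drop = FALSE]
  dz <- pred(g)
  if (!any(dz)) {
    stop_quadzone("quadzone_no_landmarks", "empty danger zone (truth)")
  }
  pts <- g[dz, , drop = FALSE]
  pts[which.max(objective(pts)), ]
}

truth_feasible <- function(spec, R, viewpoints) {
  region <- phantom_region_filter(spec)
  pred <- truth_danger_pred(spec, R, viewpoints)
  function(points) {
    points <- as_point_matrix(points)
    ok <- region(points)
    if (any(ok)) ok[ok] <- pred(points[ok, , drop = FALSE])
    ok
  }
}

# Outermost feasible parameter on a 2D probe ray (exact bisection).
truth_probe <- function(origin2, dir2, trange, step, feasible, tol = 1e-4) {
  ts <- seq(trange[1L], trange[2L], by = step)
  pts <- cbind(origin2[1L] + ts * dir2[1L], origin2[2L] + ts * dir2[2L], 0)
  ok <- feasible(pts)
  if (!any(ok)) return(NULL)
  i <- max(which(ok))
  a <- ts[i]
  b <- if (i < length(ts)) ts[i + 1L] else ts[i] + step
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (feasible(cbind(origin2[1L] + mid * dir2[1L],
                       origin2[2L] + mid * dir2[2L], 0))) a <- mid else b <- mid
  }
  c(origin2 + a * dir2, 0)
}

# G: dangerous point farthest from the canal (fan of rays out of the canal).
truth_G <- function(spec, R, viewpoints) {
  canal <- spec$obturator_canal
  obj <- function(p) sqrt(rowSums((as_point_matrix(p) -
    matrix(canal, nrow(as_point_matrix(p)), 3L, byrow = TRUE))^2))
  p0 <- truth_danger_seed(spec, R, viewpoints, obj)
  feas <- truth_feasible(spec, R, viewpoints)
  a2 <- canal[1:2]
  t0 <- sqrt(sum((p0[1:2] - a2)^2))
  th0 <- atan2(p0[2L] - a2[2L], p0[1L] - a2[1L])
  best <- p0
  fbest <- obj(p0)
  for (dth in seq(-10, 10, by = 0.05) * pi / 180) {
    u <- c(cos(th0 + dth), sin(th0 + dth))
    cand <- truth_probe(a2, u, c(max(0.5, t0 - 3), t0 + 8), 0.05, feas)
    if (is.null(cand)) next
    f <- obj(cand)
    if (f > fbest) {
      fbest <- f
      best <- cand
    }
  }
  best
}

# H: dangerous point farthest from the brim arc (region points lie inside
# the brim circle, so the objective is br - |p - bc|, maximised at the
# innermost feasible point of rays from the brim centre).
truth_H <- function(spec, R, viewpoints) {
  obj <- function(p) truth_brim_distance(spec, p)
  p0 <- truth_danger_seed(spec, R, viewpoints, obj)
  feas <- truth_feasible(spec, R, viewpoints)
  bc <- spec$brim_center
  br <- spec$brim_radius
  d0 <- sqrt(sum((p0[1:2] - bc)^2))
  th0 <- atan2(p0[2L] - bc[2L], p0[1L] - bc[1L])
  best <- p0
  fbest <- obj(p0)
  # probe inward: parameterise by distance BELOW the arc, s = br - t
  for (dth in (seq(-12, 12, by = 0.05) / br)) {
    u <- c(cos(th0 + dth), sin(th0 + dth))
    # probe along -u with negative parameters: position bc + t(-u) = bc + |t|u,
    # so maximising t minimises the distance |t| to the brim centre
    cand <- truth_probe(bc, -u, c(-(d0 + 8), -max(0.5, d0 - 8)), 0.05, feas)
    if (is.null(cand)) next
    f <- obj(cand)
    if (f > fbest) {
      fbest <- f
      best <- cand
    }
  }
  best
}

truth_brim_distance <- function(spec, points) {
  points <- as_point_matrix(points)
  d <- sqrt((points[, 1L] - spec$brim_center[1L])^2 +
            (points[, 2L] - spec$brim_center[2L])^2)
  # distance to the full circle; the arc spans well past the plate so the
  # radial distance is exact for all region points
  abs(d - spec$brim_radius)
}

truth_foot_on_brim <- function(spec, p) {
  dirv <- (p[1:2] - spec$brim_center) /
    sqrt(sum((p[1:2] - spec$brim_center)^2))
  c(spec$brim_center + spec$brim_radius * dirv, 0)
}

truth_tangent_at_foot <- function(spec, p) {
  dirv <- (p[1:2] - spec$brim_center) /
    sqrt(sum((p[1:2] - spec$brim_center)^2))
  t2 <- c(dirv[2L], -dirv[1L])
  if (t2[1L] < 0) t2 <- -t2
  t2
}

truth_parallel_to_foramen <- function(spec, p, t2) {
  q <- p[1:2] - spec$foramen_center
  a <- spec$foramen_axes[1L]
  b <- spec$foramen_axes[2L]
  Aq <- (t2[1L] / a)^2 + (t2[2L] / b)^2
  Bq <- 2 * (q[1L] * t2[1L] / a^2 + q[2L] * t2[2L] / b^2)
  Cq <- (q[1L] / a)^2 + (q[2L] / b)^2 - 1
  disc <- Bq^2 - 4 * Aq * Cq
  if (disc < 0) {
    stop_quadzone("quadzone_no_intersection",
                  "brim-parallel line misses the foramen (truth)")
  }
  ss <- c((-Bq - sqrt(disc)) / (2 * Aq), (-Bq + sqrt(disc)) / (2 * Aq))
  s <- ss[which.min(abs(ss))]
  c(p[1:2] + s * t2, 0)
}

#' Closed-form ground truth for a phantom
#'
#' For each offset and viewpoint, the shadow of the offset articular
#' sphere on the plate plane (exact segment-sphere membership plus the
#' tangent-cone conic coefficients of its boundary), the landmark points
#' E, F, G, H under the same quantifier semantics as the pipeline, and the
#' exact expected measurement record. Pure function of the spec: requires
#' a noise-free, non-lumpy phantom.
#'
#' @param spec a [phantom_spec()].
#' @param offsets shelling distances (mm).
#' @param aperture an [make_incision()] aperture; defaults to the spec's
#'   incision endpoints with 21 viewpoints.
#' @return a `phantom_truth` list: per offset the landmarks, measurement
#'   record, per-viewpoint conic coefficients; plus the occlusion
#'   predicate `occluded(points, viewpoint, d)`.
#' @export
analytic_truth <- function(spec, offsets = c(2.95, 6), aperture = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$lumpy || spec$noise_sigma > 0) {
    stop_quadzone("quadzone_truth_undefined",
                  "analytic truth requires a noise-free spherical cup")
  }
  if (is.null(aperture)) {
    aperture <- make_incision(spec$incision_proximal, spec$incision_distal)
  }
  vps <- aperture$viewpoints
  center <- spec$acetabulum_center
  per_offset <- lapply(offsets, function(d) {
    R <- spec$acetabulum_radius + d
    vd <- sqrt(rowSums((vps - matrix(center, nrow(vps), 3L,
                                     byrow = TRUE))^2))
    if (any(vd <= R)) {
      stop_quadzone("quadzone_truth_undefined",
                    "a viewpoint lies inside the offset sphere")
    }
    E <- truth_brim_boundary(spec, R, aperture$distal_end, "farthest")
    F_ <- truth_brim_boundary(spec, R, aperture$proximal_end, "nearest")
    G <- truth_G(spec, R, vps)
    H <- truth_H(spec, R, vps)
    K <- truth_foot_on_brim(spec, spec$foramen_top)
    M <- truth_foot_on_brim(spec, G)
    P <- truth_foot_on_brim(spec, H)
    N <- truth_parallel_to_foramen(spec, G, truth_tangent_at_foot(spec, G))
    Q <- truth_parallel_to_foramen(spec, H, truth_tangent_at_foot(spec, H))
    cmd <- function(a, b) sqrt(sum((a - b)^2)) / 10
    rec <- structure(list(
      subject_id = "analytic_truth", offset_d = d,
      EK = cmd(E, K), FK = cmd(F_, K), GM = cmd(G, M), GN = cmd(G, N),
      HP = cmd(H, P), HQ = cmd(H, Q),
      points = list(E = E, F = F_, G = G, H = H, K = K, M = M, N = N,
                    P = P, Q = Q)), class = "measurement_record")
    conics <- lapply(seq_len(nrow(vps)), function(i)
      shadow_conic(vps[i, ], center, R))
    list(offset = d, landmarks = list(E = E, F = F_, G = G, H = H),
         record = rec, conics = conics)
  })
  names(per_offset) <- sprintf("d_%g", offsets)
  structure(list(
    offsets = offsets,
    per_offset = per_offset,
    occluded = function(points, viewpoint, d) {
      truth_occluded(points, viewpoint, center, spec$acetabulum_radius + d)
    },
    spec = spec,
    aperture = aperture
  ), class = "phantom_truth")
}

#' Write a phantom subject in the pipeline's file input contract
#'
#' Emits `inner_surface.stl`, `acetabular_cap.stl`, `landmarks.json`
#' (including a `region_polygon` lasso around the plate) and `spec.yaml`
#' into a directory, so a generated phantom can be re-read with
#' [load_subject()].
#'
#' @param subject a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "phantom_subject"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(subject$inner_surface, file.path(dir, "inner_surface.stl"))
  write_mesh(subject$acetabular_cap, file.path(dir, "acetabular_cap.stl"))
  sp <- subject$spec
  m <- 0.5 * sp$scale
  poly <- rbind(c(sp$plate_x[1L] + m, sp$plate_y[1L] + m, 0),
                c(sp$plate_x[2L] - m, sp$plate_y[1L] + m, 0),
                c(sp$plate_x[2L] - m, sp$plate_y[2L] - m, 0),
                c(sp$plate_x[1L] + m, sp$plate_y[2L] - m, 0))
  lm <- subject$landmarks
  jsonlite::write_json(
    list(brim = lm$brim, foramen_rim = lm$foramen_rim,
         obturator_canal = lm$obturator_canal,
         foramen_top = lm$foramen_top,
         incision = list(proximal = lm$incision$proximal,
                         distal = lm$incision$distal),
         region_polygon = poly, side = "left"),
    file.path(dir, "landmarks.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(sp)
  cfg$brim_anchors <- apply(sp$brim_anchors, 1L, as.numeric,
                            simplify = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Generate a cohort of perturbed phantom specs
#'
#' Draws `n` feasible specs by perturbing the base spec's cup radius, cup
#' clearance, foramen axes and global scale with independent relative
#' Gaussian factors of standard deviation `variation` (e.g. 0.05 for 5%),
#' deterministically from `seed`. Infeasible draws are retried a bounded
#' number of times.
#'
#' @param base_spec a [phantom_spec()].
#' @param n cohort size.
#' @param variation relative standard deviation of the perturbations.
#' @param seed integer seed.
#' @return list of `phantom_spec`.
#' @export
generate_cohort <- function(base_spec, n, variation = 0.05, seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    stop_quadzone("quadzone_cohort_error", "cohort size must be >= 1")
  }
  if (variation < 0) {
    stop_quadzone("quadzone_cohort_error", "variation must be non-negative")
  }
  rng <- make_lcg(seed)
  gauss <- function() {
    u <- rng(2L)
    sqrt(-2 * log(u[1L])) * cos(2 * pi * u[2L])
  }
  base <- unclass(base_spec)
  s0 <- base$scale
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:25) {
      fac <- function() 1 + variation * gauss()
      sp <- tryCatch(
        phantom_spec(
          acetabulum_radius = base$acetabulum_radius / s0 * fac(),
          cup_clearance = base$cup_clearance / s0 * fac(),
          cup_center_xy = base$cup_center_xy / s0,
          cup_half_angle_deg = base$cup_half_angle_deg,
          plate_x = base$plate_x / s0,
          plate_y = base$plate_y / s0,
          plate_thickness = base$plate_thickness / s0,
          brim_anchors = base$brim_anchors / s0,
          foramen_center = base$foramen_center / s0,
          foramen_axes = base$foramen_axes / s0 * c(fac(), fac()),
          canal_angle_deg = base$canal_angle_deg,
          incision_proximal = base$incision_proximal / s0,
          incision_distal = base$incision_distal / s0,
          mesh_resolution = base$mesh_resolution / s0,
          entry_spacing = base$entry_spacing / s0,
          scale = s0 * fac(),
          noise_sigma = base$noise_sigma / s0,
          lumpy = base$lumpy,
          lump_amplitude = base$lump_amplitude / s0,
          seed = base$seed + i
        ), quadzone_error = function(e) NULL)
      if (!is.null(sp)) {
        out[[i]] <- sp
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_quadzone("quadzone_cohort_error",
                    sprintf("no feasible spec for subject %d after 25 draws", i))
    }
  }
  names(out) <- sprintf("phantom_%02d", seq_len(n))
  out
}
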