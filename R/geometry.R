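#' Ray-mesh intersections
#'
#' Intersects a single ray with every triangle of a mesh and returns the
#' hits ordered by distance. Hits closer than `eps` to the origin are
#' discarded (standard self-intersection guard when the origin lies on the
#' surface).
#'
#' @param mesh a [triangle_mesh()].
#' @param origin ray origin (mm).
#' @param direction ray direction; need not be unit length (t is reported in
#'   units of `direction`'s length unless `normalize = TRUE`, the default,
#'   which rescales to mm).
#' @param max_t furthest hit to keep, in mm (after normalisation).
#' @param eps minimum hit distance in mm.
#' @param normalize rescale `direction` to unit length.
#' @return a data frame with columns `t` (mm), `face` (1-based face index)
#'   and `x`, `y`, `z` (hit location), sorted by increasing `t`.
#' @export
ray_intersections <- function(mesh, origin, direction, max_t = Inf,
                              eps = 1e-6, normalize = TRUE) {
  origin <- check_point3(origin, "origin")
  direction <- as.numeric(direction)
  if (length(direction) != 3L || !all(is.finite(direction)) ||
      sqrt(sum(direction^2)) < 1e-12) {
    stop_quadzone("quadzone_invalid_argument",
                  "direction must be a non-zero finite 3-vector")
  }
  if (normalize) direction <- direction / sqrt(sum(direction^2))
  hits <- cpp_ray_hits(mesh$vertices, mesh$faces, origin, direction,
                       max_t, eps)
  t <- as.numeric(hits$t)
  face <- as.integer(hits$face)
  ord <- order(t)
  t <- t[ord]
  face <- face[ord]
  pts <- if (length(t)) {
    matrix(origin, nrow = length(t), ncol = 3L, byrow = TRUE) +
      outer(t, direction)
  } else {
    matrix(numeric(0), ncol = 3L)
  }
  data.frame(t = t, face = face,
             x = pts[, 1L][seq_along(t)], y = pts[, 2L][seq_along(t)],
             z = pts[, 3L][seq_along(t)])
}

#' Distance from points to a mesh surface
#'
#' Unsigned distance to the nearest point of the surface. With
#' `signed = TRUE` (watertight meshes only) interior points get negative
#' sign, determined by ray-crossing parity with a majority vote over three
#' fixed skew directions.
#'
#' @param mesh a [triangle_mesh()].
#' @param points a point or n x 3 matrix of points (mm).
#' @param signed return signed distance (requires a watertight mesh).
#' @return numeric vector of distances (mm).
#' @export
distance_to_surface <- function(mesh, points, signed = FALSE) {
  points <- as_point_matrix(points)
  res <- cpp_point_mesh_distance(mesh$vertices, mesh$faces, points)
  d <- as.numeric(res$distance)
  if (signed) {
    if (!is_watertight(mesh)) {
      stop_quadzone("quadzone_invalid_argument",
                    "signed distance requires a watertight mesh")
    }
    d <- d * ifelse(points_inside(mesh, points), -1, 1)
  }
  d
}

# Ray-parity interior test with a 2-of-3 vote over fixed irrational-slope
# directions (robust against rays grazing edges).
points_inside <- function(mesh, points) {
  points <- as_point_matrix(points)
  dirs <- rbind(c(0.5403023, 0.8414710, 0.1736482),
                c(-0.2873479, 0.3420201, 0.8948188),
                c(0.7660444, -0.5735764, 0.2911361))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  votes <- vapply(seq_len(3L), function(k) {
    dmat <- matrix(dirs[k, ], nrow = nrow(points), ncol = 3L, byrow = TRUE)
    counts <- cpp_ray_hit_counts(mesh$vertices, mesh$faces, points, dmat, 1e-9)
    counts %% 2L == 1L
  }, logical(nrow(points)))
  if (nrow(points) == 1L) votes <- matrix(votes, nrow = 1L)
  rowSums(votes) >= 2L
}
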