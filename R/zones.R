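# Zone classification: which entry points on the quadrilateral surface are
# hidden behind the offset acetabular shells when viewed from the incision.
# An entry point occluded by a shell from a viewpoint means a straight screw
# from that viewpoint would pass closer to the articular surface than the
# shell's clearance.

ACCEL_MIN_FACES <- 4000L

#' Occlusion mask of entry points behind an occluder from one viewpoint
#'
#' `mask[i]` is `TRUE` when the open segment from `viewpoint` to
#' `entry_points[i, ]` intersects the occluder surface, i.e. the entry
#' point lies in the occluder's shadow.
#'
#' @param entry_points n x 3 matrix of candidate entry points (mm).
#' @param occluder a [triangle_mesh()] (an offset shell).
#' @param viewpoint 3D point (mm).
#' @param eps segment-end clipping length (mm); guards against grazing
#'   self-hits at either end.
#' @return logical vector of length n.
#' @export
occluded_mask <- function(entry_points, occluder, viewpoint, eps = 1e-6) {
  entry_points <- as_point_matrix(entry_points, "entry_points")
  viewpoint <- check_point3(viewpoint, "viewpoint")
  if (n_faces(occluder) == 0L) {
    stop_quadzone("quadzone_degenerate_input", "occluder mesh is empty")
  }
  m <- cpp_occlusion_matrix(occluder$vertices, occluder$faces, entry_points,
                            matrix(viewpoint, ncol = 3L), eps,
                            ACCEL_MIN_FACES)
  if (anyNA(m)) {
    stop_quadzone("quadzone_invalid_argument",
                  "viewpoint coincides with an entry point")
  }
  m[, 1L]
}

occlusion_matrix_for <- function(occluder, entry_points, viewpoints,
                                 eps = 1e-6) {
  m <- cpp_occlusion_matrix(occluder$vertices, occluder$faces, entry_points,
                            viewpoints, eps, ACCEL_MIN_FACES)
  if (anyNA(m)) {
    stop_quadzone("quadzone_invalid_argument",
                  "a viewpoint coincides with an entry point")
  }
  m
}

#' Classify screw entry points into absolute/relative danger and safe zones
#'
#' For each entry point the shells are tested from every incision
#' viewpoint:
#' * `ABS_DANGER` - occluded by the absolute-clearance shell from **every**
#'   viewpoint: no admissible trajectory keeps even the minimal clearance.
#' * `ABS_SAFE` - clear of the margin shell from **at least one**
#'   viewpoint: some admissible trajectory keeps the clearance plus the
#'   error margin.
#' * `REL_DANGER` - neither: the minimal clearance is achievable from some
#'   direction but the margin clearance from none.
#'
#' `quantifier = "union"` flips the quantifiers (dangerous when occluded
#' from *any* viewpoint, safe only when clear from *all*); it is exposed as
#' an alternative reading of "observed at a random visual point" but the
#' default follows the escape-direction logic of the landmark definitions
#' (an entry proximal to E is safe when entered from the distal end, and
#' vice versa for F).
#'
#' @param entry_points n x 3 matrix of candidate entry points (mm).
#' @param shell_absolute shell at the absolute clearance (2.95 mm default).
#' @param shell_margin shell at the margin clearance (6 mm default).
#' @param aperture an [make_incision()] aperture.
#' @param quantifier `"intersection"` (default) or `"union"`.
#' @param eps segment clipping length (mm).
#' @return a `zone_map`: entry points, per-point `labels` (factor with
#'   levels `ABS_SAFE`, `REL_DANGER`, `ABS_DANGER`), the per-viewpoint
#'   occlusion matrices for both shells, the aperture and the shells.
#' @export
classify_zones <- function(entry_points, shell_absolute, shell_margin,
                           aperture, quantifier = c("intersection", "union"),
                           eps = 1e-6) {
  quantifier <- match.arg(quantifier)
  entry_points <- as_point_matrix(entry_points, "entry_points")
  if (!inherits(aperture, "incision_aperture")) {
    stop_quadzone("quadzone_invalid_argument",
                  "aperture must be an incision_aperture")
  }
  vp <- aperture$viewpoints
  if (nrow(vp) < 1L) {
    stop_quadzone("quadzone_invalid_argument", "empty viewpoint list")
  }
  occ_abs <- occlusion_matrix_for(shell_absolute, entry_points, vp, eps)
  occ_mar <- occlusion_matrix_for(shell_margin, entry_points, vp, eps)
  danger_abs <- if (quantifier == "intersection") {
    rowSums(occ_abs) == ncol(occ_abs)
  } else {
    rowSums(occ_abs) > 0L
  }
  safe <- if (quantifier == "intersection") {
    rowSums(!occ_mar) > 0L
  } else {
    rowSums(!occ_mar) == ncol(occ_mar)
  }
  labels <- rep("REL_DANGER", nrow(entry_points))
  labels[safe] <- "ABS_SAFE"
  labels[danger_abs] <- "ABS_DANGER"  # danger wins on (numerical) overlap
  structure(list(entry_points = entry_points,
                 labels = factor(labels,
                                 levels = c("ABS_SAFE", "REL_DANGER",
                                            "ABS_DANGER")),
                 occluded_absolute = occ_abs,
                 occluded_margin = occ_mar,
                 aperture = aperture,
                 quantifier = quantifier,
                 shell_absolute = shell_absolute,
                 shell_margin = shell_margin,
                 eps = eps),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<zone_map: %d entry points, %d viewpoints (%s)>\n  ABS_SAFE %d | REL_DANGER %d | ABS_DANGER %d\n",
    nrow(x$entry_points), nrow(x$aperture$viewpoints), x$quantifier,
    tab[["ABS_SAFE"]], tab[["REL_DANGER"]], tab[["ABS_DANGER"]]))
  invisible(x)
}

# Integer codes for overlay export: 0 safe, 1 relative, 2 absolute danger.
zone_codes <- function(zonemap) {
  unname(c(ABS_SAFE = 0L, REL_DANGER = 1L, ABS_DANGER = 2L)[
    as.character(zonemap$labels)])
}

# Dangerous set of one shell under the map's quantifier, from the stored
# occlusion matrices.
shell_danger_mask <- function(zonemap, shell = c("absolute", "margin")) {
  shell <- match.arg(shell)
  occ <- if (shell == "absolute") zonemap$occluded_absolute else
    zonemap$occluded_margin
  if (zonemap$quantifier == "intersection") {
    rowSums(occ) == ncol(occ)
  } else {
    rowSums(occ) > 0L
  }
}

shell_mesh_of <- function(zonemap, shell = c("absolute", "margin")) {
  shell <- match.arg(shell)
  if (shell == "absolute") zonemap$shell_absolute else zonemap$shell_margin
}

#' Extract the extremal landmark points E, F, G and H of a danger zone
#'
#' On the pelvic brim: `F` is the occlusion-boundary point nearest the
#' obturator canal when the shell is viewed from the **proximal** incision
#' end, and `E` the boundary point farthest from the canal when viewed from
#' the **distal** end. Within the quadrilateral region: `G` is the
#' dangerous point farthest from the obturator canal and `H` the dangerous
#' point farthest from the pelvic brim. E and F are located on the brim
#' curve by bisection of the single-viewpoint occlusion predicate; G and H
#' start from the classified entry points and are then refined by a
#' feasible pattern search in the surface plane, so their accuracy is
#' limited by the shell geometry rather than the entry-point spacing.
#'
#' @param zonemap a [classify_zones()] result.
#' @param brim pelvic brim polyline (n x 3, mm).
#' @param obturator_canal the obturator canal point (mm).
#' @param shell which shell's danger zone to analyse (`"absolute"` = the
#'   smaller clearance).
#' @param brim_step brim densification step (mm) for boundary bracketing.
#' @param refine refine G/H beyond the entry-point spacing.
#' @param region_filter optional `function(points) -> logical` restricting
#'   refinement to the analysed quadrilateral region (e.g. inside the plate
#'   boundary and outside the foramen).
#' @param surface optional `triangle_mesh`; refinement candidates are
#'   projected onto it so they stay on the bone surface.
#' @param frame optional [fit_reference_frame()] supplying the in-plane
#'   basis for refinement; fitted from the dangerous points when absent.
#' @return a `zone_landmarks` list with 3-vectors `E`, `F`, `G`, `H`.
#' @export
extract_landmarks <- function(zonemap, brim, obturator_canal,
                              shell = c("absolute", "margin"),
                              brim_step = 0.1, refine = TRUE,
                              region_filter = NULL, surface = NULL,
                              frame = NULL) {
  shell <- match.arg(shell)
  brim <- as_polyline(brim, "brim")
  obturator_canal <- check_point3(obturator_canal, "obturator_canal")
  danger <- shell_danger_mask(zonemap, shell)
  if (!any(danger)) {
    stop_quadzone("quadzone_no_landmarks",
                  "dangerous zone is empty: the shell never occludes the region")
  }
  mesh <- shell_mesh_of(zonemap, shell)
  accel <- cpp_mesh_accel(mesh$vertices, mesh$faces, ACCEL_MIN_FACES)
  vp <- zonemap$aperture$viewpoints
  eps <- zonemap$eps

  occluded_from <- function(points, viewpoint) {
    m <- cpp_occlusion_matrix_accel(accel, as_point_matrix(points),
                                    matrix(viewpoint, ncol = 3L), eps, FALSE)
    m[, 1L]
  }
  danger_pred <- function(points) {
    points <- as_point_matrix(points)
    m <- cpp_occlusion_matrix_accel(accel, points, vp, eps,
                                    zonemap$quantifier == "intersection")
    if (zonemap$quantifier == "intersection") {
      # early exit leaves NA after the first clear viewpoint, so a
      # dangerous point is exactly a complete row of TRUE
      apply(m, 1L, function(r) !anyNA(r) && all(r))
    } else {
      apply(m, 1L, function(r) isTRUE(any(r)))
    }
  }

  ends <- list(proximal = zonemap$aperture$proximal_end,
               distal = zonemap$aperture$distal_end)
  E <- brim_boundary_point(brim, ends$distal, occluded_from, obturator_canal,
                           pick = "farthest", brim_step = brim_step)
  F_ <- brim_boundary_point(brim, ends$proximal, occluded_from,
                            obturator_canal, pick = "nearest",
                            brim_step = brim_step)

  pts <- zonemap$entry_points[danger, , drop = FALSE]
  if (is.null(frame)) {
    frame <- tryCatch(fit_reference_frame(zonemap$entry_points, brim),
                      quadzone_error = function(e) NULL)
  }
  dist_canal <- function(p) sqrt(rowSums(
    (as_point_matrix(p) - matrix(obturator_canal, nrow = nrow(as_point_matrix(p)),
                                 ncol = 3L, byrow = TRUE))^2))
  brim_dense <- densify_polyline(brim, 0.25)
  dist_brim <- function(p) distance_to_polyline(brim_dense, p)

  feasible <- function(points) {
    points <- as_point_matrix(points)
    ok <- rep(TRUE, nrow(points))
    if (!is.null(region_filter)) ok <- region_filter(points)
    if (any(ok)) ok[ok] <- danger_pred(points[ok, , drop = FALSE])
    ok
  }
  spacing <- entry_spacing_estimate(pts)
  G <- pts[which.max(dist_canal(pts)), ]
  H <- pts[which.max(dist_brim(pts)), ]
  if (refine && !is.null(frame)) {
    G <- radial_extremal(G, obturator_canal, dist_canal, feasible, frame,
                         surface, spacing)
    H <- offcurve_extremal(H, brim_dense, dist_brim, feasible, frame,
                           surface, spacing)
  }

  structure(list(E = E, F = F_, G = G, H = H, shell = shell),
            class = "zone_landmarks")
}

# Boundary of the occluded set along the brim under a single viewpoint:
# densify, find occluded/clear transitions, bisect each bracket, then pick
# the boundary point nearest/farthest from the canal.
brim_boundary_point <- function(brim, viewpoint, occluded_from, canal,
                                pick = c("nearest", "farthest"),
                                brim_step = 0.1, tol = 1e-4) {
  pick <- match.arg(pick)
  dense <- densify_polyline(brim, brim_step)
  occ <- occluded_from(dense, viewpoint)
  if (all(occ)) {
    stop_quadzone("quadzone_no_landmarks",
                  "entire brim is occluded from the incision end")
  }
  if (!any(occ)) {
    stop_quadzone("quadzone_no_landmarks",
                  "shell does not occlude the brim from the incision end")
  }
  flips <- which(diff(occ) != 0L)
  boundary <- t(vapply(flips, function(i) {
    a <- dense[i, ]
    b <- dense[i + 1L, ]
    fa <- occ[i]
    while (sqrt(sum((b - a)^2)) > tol) {
      mid <- (a + b) / 2
      if (occluded_from(matrix(mid, ncol = 3L), viewpoint) == fa) {
        a <- mid
      } else {
        b <- mid
      }
    }
    (a + b) / 2
  }, numeric(3L)))
  d <- sqrt(rowSums((boundary - matrix(canal, nrow = nrow(boundary),
                                       ncol = 3L, byrow = TRUE))^2))
  boundary[if (pick == "nearest") which.min(d) else which.max(d), ]
}

# The extremal points G and H sit where a distance level set is tangent to
# the dangerous-zone boundary; a local search stalls there because the
# objective is almost flat along the curved boundary. Instead the boundary
# is located along one-dimensional probes on which the objective is
# monotone: for G, rays out of the obturator canal; for H, inward normals
# of the brim. Each probe is scanned coarsely for its outermost feasible
# point and the boundary crossing is then bisected.

probe_outermost <- function(origin2, dir2, trange, step, feasible, frame,
                            surface, tol = 0.003) {
  ts <- seq(trange[1L], trange[2L], by = step)
  lift <- function(tv) {
    p <- from_plane(frame, cbind(origin2[1L] + tv * dir2[1L],
                                 origin2[2L] + tv * dir2[2L]))
    if (!is.null(surface)) {
      p <- cpp_point_mesh_distance(surface$vertices, surface$faces, p)$nearest
    }
    p
  }
  ok <- feasible(lift(ts))
  if (!any(ok)) return(NULL)
  i <- max(which(ok))
  a <- ts[i]
  b <- if (i < length(ts)) ts[i + 1L] else ts[i] + step
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (feasible(lift(mid))) a <- mid else b <- mid
  }
  lift(a)[1L, ]
}

# G-type refinement: maximise distance from an apex point (the canal).
radial_extremal <- function(p0, apex, objective, feasible, frame, surface,
                            spacing) {
  a2 <- to_plane(frame, matrix(apex, ncol = 3L))[1L, ]
  q0 <- to_plane(frame, matrix(p0, ncol = 3L))[1L, ]
  t0 <- sqrt(sum((q0 - a2)^2))
  th0 <- atan2(q0[2L] - a2[2L], q0[1L] - a2[1L])
  best <- p0
  fbest <- objective(matrix(p0, ncol = 3L))
  for (dth in seq(-10, 10, by = 0.25) * pi / 180) {
    u <- c(cos(th0 + dth), sin(th0 + dth))
    cand <- probe_outermost(a2, u, c(max(0.5, t0 - 3 * spacing),
                                     t0 + 8 * spacing),
                            min(spacing / 4, 0.35), feasible, frame, surface)
    if (is.null(cand)) next
    f <- objective(matrix(cand, ncol = 3L))
    if (f > fbest) {
      fbest <- f
      best <- cand
    }
  }
  best
}

# H-type refinement: maximise distance from the brim curve. Probes start
# on the brim near the foot of p0 and run along the inward normal.
offcurve_extremal <- function(p0, brim_dense, objective, feasible, frame,
                              surface, spacing) {
  poly2 <- to_plane(frame, brim_dense)
  q0 <- to_plane(frame, matrix(p0, ncol = 3L))[1L, ]
  cl <- closest_on_polyline(cbind(poly2, 0), matrix(c(q0, 0), ncol = 3L))
  foot2 <- cl$points[1L, 1:2]
  f0 <- cl$dist[1L]
  best <- p0
  fbest <- objective(matrix(p0, ncol = 3L))
  # arc-length positions of the densified brim samples
  seglen <- sqrt(rowSums(diff(poly2)^2))
  s <- c(0, cumsum(seglen))
  s_foot <- s[cl$seg[1L]] + cl$tloc[1L] * seglen[cl$seg[1L]]
  sel <- which(abs(s - s_foot) <= 8 * spacing)
  sel <- sel[sel > 1L & sel < nrow(poly2)]
  for (j in sel) {
    tan2 <- poly2[j + 1L, ] - poly2[j - 1L, ]
    tan2 <- tan2 / sqrt(sum(tan2^2))
    n2 <- c(-tan2[2L], tan2[1L])
    if (sum(n2 * (q0 - foot2)) < 0) n2 <- -n2
    cand <- probe_outermost(poly2[j, ], n2,
                            c(max(0.5, f0 - 3 * spacing), f0 + 8 * spacing),
                            min(spacing / 4, 0.35), feasible, frame, surface)
    if (is.null(cand)) next
    f <- objective(matrix(cand, ncol = 3L))
    if (f > fbest) {
      fbest <- f
      best <- cand
    }
  }
  best
}

entry_spacing_estimate <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(1)
  idx <- if (n > 200L) unique(round(seq(1L, n, length.out = 200L))) else
    seq_len(n)
  nn <- vapply(idx, function(i) {
    d2 <- rowSums((pts - matrix(pts[i, ], n, 3L, byrow = TRUE))^2)
    sqrt(min(d2[-i]))
  }, numeric(1L))
  max(stats::median(nn), 0.05)
}
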