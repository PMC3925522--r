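# Landmark constructions K, M, N, P, Q and the distance measurements
# EK, FK, GM, GN, HP, HQ. "Perpendicular / parallel to the pelvic brim" is
# evaluated in the best-fit plane of the quadrilateral region using the
# local brim tangent at the nearest brim point: perpendicularity to a 3D
# space curve is otherwise underdetermined. Distances are straight-line 3D
# segment lengths, reported in centimetres.

#' Best-fit working plane of the quadrilateral region
#'
#' Least-squares plane through the region points plus an in-plane brim
#' tangent direction (the principal direction of the brim projected into
#' the plane). All perpendicular/parallel constructions are carried out in
#' this frame.
#'
#' @param region_points n x 3 matrix (mm), at least 3 non-collinear points.
#' @param brim pelvic brim polyline.
#' @return a `reference_frame`: `origin`, unit `normal`, in-plane unit
#'   `tangent` (brim direction) and `bitangent`.
#' @export
fit_reference_frame <- function(region_points, brim) {
  region_points <- as_point_matrix(region_points, "region_points")
  brim <- as_polyline(brim, "brim")
  if (nrow(region_points) < 3L) {
    stop_quadzone("quadzone_frame_error",
                  "need at least 3 region points to fit a plane")
  }
  pc <- prcomp(region_points, center = TRUE)
  if (pc$sdev[2L] < 1e-9) {
    stop_quadzone("quadzone_frame_error",
                  "region points are collinear; plane undefined")
  }
  normal <- pc$rotation[, 3L]
  # deterministic orientation: largest-magnitude component positive
  k <- which.max(abs(normal))
  if (normal[k] < 0) normal <- -normal
  origin <- pc$center
  bproj <- project_out(brim, normal)
  bpc <- prcomp(bproj, center = TRUE)
  tangent <- bpc$rotation[, 1L]
  tangent <- tangent - sum(tangent * normal) * normal
  tl <- sqrt(sum(tangent^2))
  if (tl < 1e-9) {
    stop_quadzone("quadzone_frame_error",
                  "brim is perpendicular to the region plane")
  }
  tangent <- tangent / tl
  k <- which.max(abs(tangent))
  if (tangent[k] < 0) tangent <- -tangent
  bitangent <- c(normal[2L] * tangent[3L] - normal[3L] * tangent[2L],
                 normal[3L] * tangent[1L] - normal[1L] * tangent[3L],
                 normal[1L] * tangent[2L] - normal[2L] * tangent[1L])
  structure(list(origin = origin, normal = normal, tangent = tangent,
                 bitangent = bitangent),
            class = "reference_frame")
}

project_out <- function(points, normal) {
  points - outer(as.numeric(points %*% normal), normal)
}

# 3D -> in-plane 2D coordinates and back.
to_plane <- function(frame, points) {
  points <- as_point_matrix(points)
  rel <- points - matrix(frame$origin, nrow(points), 3L, byrow = TRUE)
  cbind(as.numeric(rel %*% frame$tangent),
        as.numeric(rel %*% frame$bitangent))
}

from_plane <- function(frame, uv) {
  uv <- as.matrix(uv)
  if (is.null(dim(uv)) || ncol(uv) == 1L) uv <- matrix(uv, ncol = 2L)
  matrix(frame$origin, nrow(uv), 3L, byrow = TRUE) +
    outer(uv[, 1L], frame$tangent) + outer(uv[, 2L], frame$bitangent)
}

#' Foot of the perpendicular from a point to a polyline
#'
#' The point and the polyline are projected into the frame plane; the foot
#' is the closest point of the projected polyline (for a smooth curve this
#' is the perpendicular foot through the local tangent; past the ends it
#' degrades gracefully to the nearest endpoint). The result lies in the
#' frame plane.
#'
#' @param point 3D point (mm).
#' @param target_polyline polyline (n x 3, mm).
#' @param frame a [fit_reference_frame()].
#' @return 3D foot point (mm).
#' @export
foot_of_perpendicular <- function(point, target_polyline, frame) {
  point <- check_point3(point, "point")
  target_polyline <- as_polyline(target_polyline, "target_polyline")
  p2 <- to_plane(frame, matrix(point, ncol = 3L))
  poly2 <- to_plane(frame, target_polyline)
  cl <- closest_on_polyline(cbind(poly2, 0), cbind(p2, 0))
  from_plane(frame, cl$points[1L, 1:2, drop = FALSE])[1L, ]
}

#' Intersection of a brim-parallel line with a polyline
#'
#' The infinite line through `point` along `brim_tangent`, evaluated in the
#' frame plane, is intersected with the projected target polyline; the
#' intersection nearest to the source point is returned.
#'
#' @param point 3D point (mm).
#' @param brim_tangent direction (3-vector); only its in-plane component is
#'   used.
#' @param target_polyline polyline to intersect (e.g. the obturator foramen
#'   rim).
#' @param frame a [fit_reference_frame()].
#' @return 3D intersection point (mm) in the frame plane.
#' @export
line_parallel_intersection <- function(point, brim_tangent, target_polyline,
                                       frame) {
  point <- check_point3(point, "point")
  brim_tangent <- as.numeric(brim_tangent)
  target_polyline <- as_polyline(target_polyline, "target_polyline")
  p2 <- to_plane(frame, matrix(point, ncol = 3L))[1L, ]
  t2 <- c(sum(brim_tangent * frame$tangent),
          sum(brim_tangent * frame$bitangent))
  tl <- sqrt(sum(t2^2))
  if (tl < 1e-12) {
    stop_quadzone("quadzone_invalid_argument",
                  "brim tangent has no in-plane component")
  }
  t2 <- t2 / tl
  poly2 <- to_plane(frame, target_polyline)
  a <- poly2[-nrow(poly2), , drop = FALSE]
  b <- poly2[-1L, , drop = FALSE]
  hits <- numeric(0)
  for (i in seq_len(nrow(a))) {
    ab <- b[i, ] - a[i, ]
    det <- t2[1L] * (-ab[2L]) - t2[2L] * (-ab[1L])
    if (abs(det) < 1e-14) next
    rhs <- a[i, ] - p2
    s <- (rhs[1L] * (-ab[2L]) - rhs[2L] * (-ab[1L])) / det
    u <- (t2[1L] * rhs[2L] - t2[2L] * rhs[1L]) / det
    if (u >= -1e-9 && u <= 1 + 1e-9) hits <- c(hits, s)
  }
  if (!length(hits)) {
    stop_quadzone("quadzone_no_intersection",
                  "brim-parallel line does not intersect the target polyline")
  }
  s <- hits[which.min(abs(hits))]
  from_plane(frame, matrix(p2 + s * t2, ncol = 2L))[1L, ]
}

# In-plane local brim tangent at the brim point nearest to `point`.
local_brim_tangent <- function(brim, point, frame) {
  poly2 <- to_plane(frame, brim)
  p2 <- to_plane(frame, matrix(point, ncol = 3L))
  cl <- closest_on_polyline(cbind(poly2, 0), cbind(p2, 0))
  s <- cl$seg[1L]
  tan2 <- poly2[s + 1L, ] - poly2[s, ]
  tan3 <- tan2[1L] * frame$tangent + tan2[2L] * frame$bitangent
  tan3 / sqrt(sum(tan3^2))
}

#' Measure the landmark distances EK, FK, GM, GN, HP, HQ for one subject
#'
#' Constructs the auxiliary points relative to the pelvic brim and the
#' obturator foramen: `K` is the perpendicular foot of the foramen top
#' point on the brim; `M` and `P` are the perpendicular feet of `G` and `H`
#' on the brim; `N` and `Q` are the intersections of the brim-parallel
#' lines through `G` and `H` with the foramen rim. All constructions use
#' the best-fit plane and the local brim tangent; distances are straight
#' 3D segment lengths converted to centimetres.
#'
#' @param landmarks a [extract_landmarks()] result (points E, F, G, H).
#' @param brim pelvic brim polyline (mm).
#' @param foramen_rim obturator foramen rim polyline (mm).
#' @param foramen_top top point of the obturator foramen (mm).
#' @param frame a [fit_reference_frame()].
#' @param subject_id subject label.
#' @param offset_d shelling distance (mm) the landmarks were derived from.
#' @return a `measurement_record` with the six distances (cm) and the
#'   constructed points.
#' @export
measure_record <- function(landmarks, brim, foramen_rim, foramen_top, frame,
                           subject_id = "subject", offset_d = NA_real_) {
  brim <- as_polyline(brim, "brim")
  foramen_rim <- as_polyline(foramen_rim, "foramen_rim")
  foramen_top <- check_point3(foramen_top, "foramen_top")
  with_landmark <- function(name, expr) {
    tryCatch(expr, quadzone_error = function(e) {
      stop_quadzone("quadzone_no_intersection",
                    sprintf("construction of point %s failed: %s", name,
                            conditionMessage(e)))
    })
  }
  K <- with_landmark("K", foot_of_perpendicular(foramen_top, brim, frame))
  M <- with_landmark("M", foot_of_perpendicular(landmarks$G, brim, frame))
  P <- with_landmark("P", foot_of_perpendicular(landmarks$H, brim, frame))
  tG <- local_brim_tangent(brim, landmarks$G, frame)
  tH <- local_brim_tangent(brim, landmarks$H, frame)
  N <- with_landmark("N",
    line_parallel_intersection(landmarks$G, tG, foramen_rim, frame))
  Q <- with_landmark("Q",
    line_parallel_intersection(landmarks$H, tH, foramen_rim, frame))
  seg_cm <- function(a, b) sqrt(sum((a - b)^2)) / 10
  rec <- structure(list(
    subject_id = subject_id, offset_d = offset_d,
    EK = seg_cm(landmarks$E, K), FK = seg_cm(landmarks$F, K),
    GM = seg_cm(landmarks$G, M), GN = seg_cm(landmarks$G, N),
    HP = seg_cm(landmarks$H, P), HQ = seg_cm(landmarks$H, Q),
    points = list(E = landmarks$E, F = landmarks$F, G = landmarks$G,
                  H = landmarks$H, K = K, M = M, N = N, P = P, Q = Q)),
    class = "measurement_record")
  d6 <- unlist(rec[c("EK", "FK", "GM", "GN", "HP", "HQ")])
  if (!all(is.finite(d6)) || any(d6 < 0)) {
    stop_quadzone("quadzone_invalid_argument",
                  "measured distances must be finite and non-negative")
  }
  rec
}

#' @export
as.data.frame.measurement_record <- function(x, ...) {
  data.frame(subject_id = x$subject_id, offset_d = x$offset_d,
             EK = x$EK, FK = x$FK, GM = x$GM, GN = x$GN, HP = x$HP,
             HQ = x$HQ, stringsAsFactors = FALSE)
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf(
    "<measurement_record %s, shell %.4g mm>\n  EK %.2f | FK %.2f | GM %.2f | GN %.2f | HP %.2f | HQ %.2f (cm)\n",
    x$subject_id, x$offset_d, x$EK, x$FK, x$GM, x$GN, x$HP, x$HQ))
  invisible(x)
}

#' Aggregate per-subject measurements into a cohort summary
#'
#' Arithmetic mean, minimum and maximum of each of the six distances per
#' shelling distance, formatted as `"mean (min-max)"` with two decimals in
#' centimetres (one row per shell).
#'
#' @param records list of [measure_record()] results.
#' @return a `cohort_summary`: `stats` (long data frame with mean/min/max/n)
#'   and `table` (formatted wide layout, rows = shelling distances).
#' @export
aggregate_cohort <- function(records) {
  if (inherits(records, "measurement_record")) records <- list(records)
  if (!length(records)) {
    stop_quadzone("quadzone_empty_summary", "no measurement records to aggregate")
  }
  df <- do.call(rbind, lapply(records, as.data.frame))
  meas <- c("EK", "FK", "GM", "GN", "HP", "HQ")
  long <- do.call(rbind, lapply(split(df, df$offset_d), function(g) {
    do.call(rbind, lapply(meas, function(m) {
      data.frame(offset_d = g$offset_d[1L], measurement = m,
                 mean = mean(g[[m]]), min = min(g[[m]]), max = max(g[[m]]),
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  }))
  rownames(long) <- NULL
  wide <- do.call(rbind, lapply(split(long, long$offset_d), function(g) {
    row <- setNames(
      lapply(meas, function(m) {
        r <- g[g$measurement == m, ]
        sprintf("%.2f (%.2f–%.2f)", r$mean, r$min, r$max)
      }), meas)
    cbind(data.frame(model = sprintf("%g mm", g$offset_d[1L]),
                     stringsAsFactors = FALSE),
          as.data.frame(row, stringsAsFactors = FALSE))
  }))
  rownames(wide) <- NULL
  structure(list(stats = long, table = wide), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: length and range of the landmark distances (cm)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
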