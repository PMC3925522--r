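# Per-subject and cohort orchestration: build shells, classify zones,
# extract landmarks, measure, aggregate, export.

#' Run configuration
#'
#' @param offsets the two shelling distances in mm, strictly increasing:
#'   the absolute clearance and the margin clearance. Defaults to
#'   `c(2.95, 6)` (subchondral bone + screw radius, and the same plus a
#'   3 mm insertion-error allowance).
#' @param voxel_pitch distance-field grid pitch for shell construction
#'   (mm); the shell is accurate to about twice the pitch.
#' @param n_viewpoints number of viewpoints sampled on the incision.
#' @param quantifier `"intersection"` (dangerous = occluded from every
#'   viewpoint) or `"union"` (occluded from any viewpoint); see
#'   [classify_zones()].
#' @param brim_step brim densification step for E/F bracketing (mm).
#' @param refine refine G/H beyond the entry grid spacing.
#' @param out_dir optional output directory for reports and overlays.
#' @param seed integer seed recorded in outputs (the pipeline itself is
#'   deterministic).
#' @return a `quadzone_config` list.
#' @export
quadzone_config <- function(offsets = c(2.95, 6), voxel_pitch = 0.5,
                            n_viewpoints = 21L,
                            quantifier = c("intersection", "union"),
                            brim_step = 0.1, refine = TRUE,
                            out_dir = NULL, seed = 1L) {
  quantifier <- match.arg(quantifier)
  offsets <- as.numeric(offsets)
  if (length(offsets) != 2L || any(!is.finite(offsets)) ||
      any(offsets <= 0) || diff(offsets) <= 0) {
    stop_quadzone("quadzone_invalid_argument",
                  "offsets must be two strictly increasing positive distances")
  }
  structure(list(offsets = offsets, voxel_pitch = voxel_pitch,
                 n_viewpoints = as.integer(n_viewpoints),
                 quantifier = quantifier, brim_step = brim_step,
                 refine = isTRUE(refine), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "quadzone_config")
}

#' Load a subject from mesh and landmark files
#'
#' The landmark JSON must contain `brim` (polyline), `foramen_rim`
#' (polyline), `obturator_canal`, `foramen_top` and `incision` with
#' `proximal`/`distal` endpoints (all in mm, the mesh coordinate frame);
#' optionally `region_polygon` (in-plane lasso delimiting the analysed
#' quadrilateral region) and `side` ("left"/"right").
#'
#' @param inner_surface_path mesh file of the hemipelvis inner surface.
#' @param acetabular_cap_path mesh file of the articular sub-surface.
#' @param landmarks_path landmark JSON file.
#' @return a `quadzone_subject`.
#' @export
load_subject <- function(inner_surface_path, acetabular_cap_path,
                         landmarks_path) {
  lm <- jsonlite::read_json(landmarks_path, simplifyVector = TRUE)
  need <- c("brim", "foramen_rim", "obturator_canal", "foramen_top",
            "incision")
  miss <- setdiff(need, names(lm))
  if (length(miss)) {
    stop_quadzone("quadzone_input_contract",
                  sprintf("landmark file is missing key(s): %s",
                          paste(miss, collapse = ", ")))
  }
  if (!all(c("proximal", "distal") %in% names(lm$incision))) {
    stop_quadzone("quadzone_input_contract",
                  "landmark key 'incision' must contain proximal and distal")
  }
  structure(list(
    inner_surface = load_mesh(inner_surface_path),
    acetabular_cap = load_mesh(acetabular_cap_path),
    landmarks = list(
      brim = as_polyline(lm$brim, "brim"),
      foramen_rim = as_polyline(lm$foramen_rim, "foramen_rim"),
      obturator_canal = check_point3(lm$obturator_canal, "obturator_canal"),
      foramen_top = check_point3(lm$foramen_top, "foramen_top"),
      incision = list(proximal = check_point3(lm$incision$proximal,
                                              "incision proximal"),
                      distal = check_point3(lm$incision$distal,
                                            "incision distal"))),
    region_polygon = if (!is.null(lm$region_polygon))
      as.matrix(lm$region_polygon) else NULL,
    side = if (!is.null(lm$side)) lm$side else "left",
    subject_id = sub("\\.json$", "", basename(landmarks_path))
  ), class = "quadzone_subject")
}

subject_id_of <- function(subject) {
  if (!is.null(subject$subject_id)) subject$subject_id else "phantom"
}

mirror_x_points <- function(p) {
  p <- as_point_matrix(p)
  p[, 1L] <- -p[, 1L]
  p
}

mirror_x_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  triangle_mesh(v, mesh$faces[, c(1L, 3L, 2L)], name = mesh$name,
                validate = FALSE)
}

# Mirror a right-side subject into the canonical left frame (x -> -x).
mirror_subject <- function(subject) {
  subject$inner_surface <- mirror_x_mesh(subject$inner_surface)
  subject$acetabular_cap <- mirror_x_mesh(subject$acetabular_cap)
  lm <- subject$landmarks
  lm$brim <- mirror_x_points(lm$brim)
  lm$foramen_rim <- mirror_x_points(lm$foramen_rim)
  lm$obturator_canal <- as.numeric(mirror_x_points(lm$obturator_canal))
  lm$foramen_top <- as.numeric(mirror_x_points(lm$foramen_top))
  lm$incision$proximal <- as.numeric(mirror_x_points(lm$incision$proximal))
  lm$incision$distal <- as.numeric(mirror_x_points(lm$incision$distal))
  subject$landmarks <- lm
  if (!is.null(subject$entry_points)) {
    subject$entry_points <- mirror_x_points(subject$entry_points)
  }
  if (!is.null(subject$region_filter)) {
    rf <- subject$region_filter
    subject$region_filter <- function(points) rf(mirror_x_points(points))
  }
  if (!is.null(subject$region_polygon)) {
    subject$region_polygon[, 1L] <- -subject$region_polygon[, 1L]
  }
  subject
}

subject_entry_points <- function(subject, config) {
  if (!is.null(subject$entry_points)) {
    return(subject$entry_points)
  }
  v <- subject$inner_surface$vertices
  if (is.null(subject$region_polygon)) {
    stop_quadzone("quadzone_input_contract",
                  "subject provides neither entry_points nor region_polygon")
  }
  frame <- fit_reference_frame(v, subject$landmarks$brim)
  poly <- subject$region_polygon
  if (ncol(poly) == 2L) poly <- cbind(poly, 0)
  poly2 <- to_plane(frame, poly)
  keep <- points_in_polygon(to_plane(frame, v), poly2)
  # a closed surface has two sheets inside the lasso; keep the sheet that
  # faces the incision (candidate entry points lie on the exposed side)
  nc <- as.numeric((v - matrix(frame$origin, nrow(v), 3L,
                               byrow = TRUE)) %*% frame$normal)
  inc_mid <- (subject$landmarks$incision$proximal +
              subject$landmarks$incision$distal) / 2
  sgn <- sign(sum((inc_mid - frame$origin) * frame$normal))
  if (sgn < 0) nc <- -nc
  span <- diff(range(nc))
  keep <- keep & nc >= max(nc[keep]) - 0.15 * max(span, 1e-9)
  if (!any(keep)) {
    stop_quadzone("quadzone_input_contract",
                  "region_polygon selects no inner-surface vertices")
  }
  v[keep, , drop = FALSE]
}

# Region filter for lasso-delimited subjects: inside the polygon and on
# the entry sheet.
polygon_region_filter <- function(subject, frame, entry) {
  poly <- subject$region_polygon
  if (ncol(poly) == 2L) poly <- cbind(poly, 0)
  poly2 <- to_plane(frame, poly)
  nc_entry <- range(as.numeric((entry - matrix(frame$origin, nrow(entry), 3L,
                                               byrow = TRUE)) %*% frame$normal))
  function(points) {
    points <- as_point_matrix(points)
    nc <- as.numeric((points - matrix(frame$origin, nrow(points), 3L,
                                      byrow = TRUE)) %*% frame$normal)
    points_in_polygon(to_plane(frame, points), poly2) &
      nc >= nc_entry[1L] - 1 & nc <= nc_entry[2L] + 1
  }
}

# Even-odd rule point-in-polygon (2D).
points_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(p))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- (yi > p[, 2L]) != (yj > p[, 2L])
    xint <- (xj - xi) * (p[, 2L] - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & p[, 1L] < xint)
    j <- i
  }
  inside
}

#' Run the full zone analysis for one subject
#'
#' Builds the two offset shells of the acetabular cap, classifies the
#' quadrilateral entry points from the incision viewpoints, extracts the
#' landmarks E, F, G, H for each shell and measures EK...HQ. With
#' `config$out_dir` set, writes `measurements.csv`, `landmarks.json`,
#' `zones.ply` (entry-point cloud with a per-vertex `zone` property) and
#' `effective_config.yaml`.
#'
#' @param subject a `phantom_subject` ([generate_phantom()]), a
#'   [phantom_spec()], or a [load_subject()] result.
#' @param config a [quadzone_config()].
#' @return a `quadzone_result`: `zonemap`, per-offset `landmarks` and
#'   `records`, `frame`, `aperture`, `shells`.
#' @export
run_subject <- function(subject, config = quadzone_config()) {
  stopifnot(inherits(config, "quadzone_config"))
  if (inherits(subject, "phantom_spec")) subject <- generate_phantom(subject)
  mirrored <- identical(subject$side, "right")
  if (mirrored) subject <- mirror_subject(subject)
  lm <- subject$landmarks
  aperture <- make_incision(lm$incision$proximal, lm$incision$distal,
                            config$n_viewpoints)
  entry <- subject_entry_points(subject, config)
  shells <- lapply(config$offsets, function(d) {
    offset_surface(subject$acetabular_cap, d,
                   voxel_pitch = config$voxel_pitch)
  })
  names(shells) <- sprintf("d_%g", config$offsets)
  zonemap <- classify_zones(entry, shells[[1L]], shells[[2L]], aperture,
                            quantifier = config$quantifier)
  frame <- fit_reference_frame(entry, lm$brim)
  region_filter <- subject$region_filter
  if (is.null(region_filter) && !is.null(subject$region_polygon)) {
    region_filter <- polygon_region_filter(subject, frame, entry)
  }
  sides <- c("absolute", "margin")
  per <- lapply(seq_along(config$offsets), function(i) {
    lms <- extract_landmarks(zonemap, lm$brim, lm$obturator_canal,
                             shell = sides[i], brim_step = config$brim_step,
                             refine = config$refine,
                             region_filter = region_filter,
                             surface = subject$inner_surface,
                             frame = frame)
    rec <- measure_record(lms, lm$brim, lm$foramen_rim, lm$foramen_top,
                          frame, subject_id = subject_id_of(subject),
                          offset_d = config$offsets[i])
    list(landmarks = lms, record = rec)
  })
  names(per) <- names(shells)
  res <- structure(list(
    zonemap = zonemap,
    landmarks = lapply(per, `[[`, "landmarks"),
    records = lapply(per, `[[`, "record"),
    frame = frame,
    aperture = aperture,
    shells = shells,
    subject_id = subject_id_of(subject),
    mirrored = mirrored,
    config = config
  ), class = "quadzone_result")
  if (mirrored) res <- mirror_result(res)
  if (!is.null(config$out_dir)) export_result(res, config)
  res
}

mirror_result <- function(res) {
  res$zonemap$entry_points <- mirror_x_points(res$zonemap$entry_points)
  res$landmarks <- lapply(res$landmarks, function(l) {
    for (nm in c("E", "F", "G", "H")) l[[nm]][1L] <- -l[[nm]][1L]
    l
  })
  res$records <- lapply(res$records, function(r) {
    r$points <- lapply(r$points, function(p) {
      p[1L] <- -p[1L]
      p
    })
    r
  })
  res
}

export_result <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- do.call(rbind, lapply(res$records, as.data.frame))
  write.csv(df, file.path(config$out_dir, "measurements.csv"),
            row.names = FALSE)
  lj <- lapply(res$records, function(r) lapply(r$points, as.numeric))
  jsonlite::write_json(lj, file.path(config$out_dir, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)
  export_zone_overlay(res$zonemap,
                      file.path(config$out_dir, "zones.ply"))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, file.path(config$out_dir, "effective_config.yaml"))
  invisible(NULL)
}

#' Export a zone map as a PLY point cloud with a per-vertex zone property
#'
#' Zone codes: 0 = absolute safe, 1 = relatively dangerous, 2 = absolute
#' dangerous.
#'
#' @param zonemap a [classify_zones()] result.
#' @param path output PLY path.
#' @return the path, invisibly.
#' @export
export_zone_overlay <- function(zonemap, path) {
  v <- zonemap$entry_points
  z <- zone_codes(zonemap)
  header <- c("ply", "format ascii 1.0",
              "comment quadzone entry-point zone overlay",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              "property int zone",
              "element face 0",
              "property list uchar int vertex_indices",
              "end_header")
  writeLines(c(header,
               sprintf("%.9g %.9g %.9g %d", v[, 1L], v[, 2L], v[, 3L], z)),
             path)
  invisible(path)
}

#' Run a cohort of subjects and aggregate the measurements
#'
#' Per-subject failures are recorded and skipped (batch morphometry
#' practice); the run fails only when every subject fails.
#'
#' @param subjects list of subjects (specs, phantom subjects or loaded
#'   subjects).
#' @param config a [quadzone_config()].
#' @return a `quadzone_cohort`: `summary` ([aggregate_cohort()]),
#'   `results`, `failures`.
#' @export
run_cohort <- function(subjects, config = quadzone_config()) {
  if (!length(subjects)) {
    stop_quadzone("quadzone_cohort_error", "no subjects supplied")
  }
  results <- list()
  failures <- list()
  for (i in seq_along(subjects)) {
    id <- if (!is.null(names(subjects)) && nzchar(names(subjects)[i]))
      names(subjects)[i] else sprintf("subject_%02d", i)
    sub_cfg <- config
    sub_cfg$out_dir <- if (!is.null(config$out_dir))
      file.path(config$out_dir, id) else NULL
    r <- tryCatch(run_subject(subjects[[i]], sub_cfg), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[id]] <- conditionMessage(r)
    } else {
      r$subject_id <- id
      for (k in seq_along(r$records)) r$records[[k]]$subject_id <- id
      results[[id]] <- r
    }
  }
  if (!length(results)) {
    stop_quadzone("quadzone_cohort_error",
                  sprintf("all %d subjects failed; first error: %s",
                          length(subjects), failures[[1L]]))
  }
  records <- unlist(lapply(results, `[[`, "records"), recursive = FALSE)
  summary <- aggregate_cohort(records)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary$table, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    df <- do.call(rbind, lapply(records, as.data.frame))
    write.csv(df, file.path(config$out_dir, "measurements.csv"),
              row.names = FALSE)
    if (length(failures)) {
      writeLines(sprintf("%s\t%s", names(failures), unlist(failures)),
                 file.path(config$out_dir, "failures.tsv"))
    }
  }
  structure(list(summary = summary, results = results, failures = failures),
            class = "quadzone_cohort")
}

#' @export
print.quadzone_result <- function(x, ...) {
  cat(sprintf("<quadzone_result %s>\n", x$subject_id))
  print(x$zonemap)
  for (nm in names(x$records)) print(x$records[[nm]])
  invisible(x)
}

#' @export
print.quadzone_cohort <- function(x, ...) {
  cat(sprintf("<quadzone_cohort: %d subjects, %d failed>\n",
              length(x$results), length(x$failures)))
  print(x$summary)
  invisible(x)
}
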