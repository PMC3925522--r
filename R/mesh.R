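#' Triangle surface mesh
#'
#' Constructs a validated triangle mesh. Coordinates are millimetres
#' throughout the package. Validation merges duplicate vertices within
#' `weld_tol` (STL stores each facet independently, so welding is required
#' before any manifold query), drops faces with repeated vertex indices or
#' (near-)zero area, and checks that all coordinates are finite and all face
#' indices are in range.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param name free-text label carried through reports.
#' @param weld_tol vertex merge tolerance in mm.
#' @param validate set to `FALSE` only for meshes already produced by
#'   package code (skips welding and degeneracy checks).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1L, 2L, 3L)))
#' n_faces(m)
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", weld_tol = 1e-6,
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) {
    stop_quadzone("quadzone_invalid_argument", "vertices must have 3 columns")
  }
  if (ncol(faces) != 3L) {
    stop_quadzone("quadzone_invalid_argument", "faces must have 3 columns")
  }
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    stop_quadzone("quadzone_degenerate_input", "mesh has no vertices or faces")
  }
  if (!all(is.finite(vertices))) {
    stop_quadzone("quadzone_invalid_argument",
                  "mesh coordinates must all be finite")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_quadzone("quadzone_invalid_argument", "face index out of range")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (validate) {
    w <- cpp_weld(vertices, weld_tol)
    vertices <- w$vertices
    faces <- matrix(w$map[faces], ncol = 3L)
    keep <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
      faces[, 1L] != faces[, 3L]
    faces <- faces[keep, , drop = FALSE]
    if (nrow(faces) > 0L) {
      areas <- face_areas(vertices, faces)
      faces <- faces[areas > 1e-12, , drop = FALSE]
    }
    if (nrow(faces) == 0L) {
      stop_quadzone("quadzone_degenerate_input",
                    "mesh has no non-degenerate faces after validation")
    }
    storage.mode(faces) <- "integer"
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  u <- vertices[faces[, 2L], , drop = FALSE] - a
  v <- vertices[faces[, 3L], , drop = FALSE] - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces%s>\n", x$name,
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `triangle_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Is a mesh watertight?
#'
#' A mesh is treated as watertight when every edge is shared by exactly two
#' faces (orientation is not checked). Watertightness is required before a
#' signed inside/outside distance query is meaningful.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  # Exact numeric edge keys: indices stay far below 2^26, so the packed
  # key is exactly representable as a double.
  key <- pmin(e[, 1L], e[, 2L]) * (nrow(mesh$vertices) + 1) +
    pmax(e[, 1L], e[, 2L])
  counts <- rle(sort(key))$lengths
  all(counts == 2L)
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2L, min),
        hi = apply(mesh$vertices, 2L, max))
}

#' Mean edge length of a mesh
#' @param mesh a `triangle_mesh`.
#' @return mean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  d <- v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
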