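# Mesh file I/O. STL is read in both the ASCII and the little-endian binary
# dialect (auto-detected); PLY is read/written in ASCII with optional
# per-vertex integer properties (used for zone overlays); OBJ covers the
# v/f subset.

#' Load a surface mesh from STL, PLY or OBJ
#'
#' @param path file path.
#' @param format `"auto"` (by extension) or one of `"stl"`, `"ply"`, `"obj"`.
#' @param weld_tol vertex merge tolerance (mm); STL facets always carry
#'   duplicated corner coordinates, which are merged here.
#' @param name mesh label; defaults to the file name.
#' @return a [triangle_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      weld_tol = 1e-6, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_quadzone("quadzone_format_error", sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj")) {
      stop_quadzone("quadzone_format_error",
                    sprintf("cannot infer mesh format from extension '%s'", ext))
    }
    format <- ext
  }
  raw <- switch(format,
    stl = read_stl_raw(path),
    ply = read_ply_raw(path),
    obj = read_obj_raw(path)
  )
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L) {
    stop_quadzone("quadzone_degenerate_input",
                  sprintf("empty mesh in %s", path))
  }
  triangle_mesh(raw$vertices, raw$faces,
                name = if (is.null(name)) basename(path) else name,
                weld_tol = weld_tol)
}

#' Write a surface mesh to STL, PLY or OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format inferred from the extension unless given.
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`.
#' @param binary write binary STL instead of ASCII.
#' @param vertex_labels optional integer vector (one per vertex) stored as a
#'   per-vertex `zone` property; PLY only.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       binary = FALSE, vertex_labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
  }
  switch(format,
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path, vertex_labels = vertex_labels),
    obj = write_obj(mesh, path),
    stop_quadzone("quadzone_format_error",
                  sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

# -- STL ---------------------------------------------------------------------

stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(ntri) || is.na(ntri)) return(FALSE)
  # A binary STL has exactly 84 + 50 * ntri bytes; the "solid" prefix alone
  # is not reliable because some binary exporters use it in the header.
  size == 84 + 50 * as.numeric(ntri)
}

read_stl_raw <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("no STL facets found in %s", path))
  }
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- vapply(toks, length, 1L) != 4L
  if (any(bad)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("malformed STL vertex line in %s", path))
  }
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L, byrow = TRUE))
  if (anyNA(coords) || nrow(coords) %% 3L != 0L) {
    stop_quadzone("quadzone_format_error",
                  sprintf("malformed STL facet data in %s", path))
  }
  nf <- nrow(coords) / 3L
  list(vertices = coords,
       faces = matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  body <- readBin(con, "raw", 50L * as.numeric(ntri))
  if (length(body) != 50L * ntri) {
    stop_quadzone("quadzone_format_error",
                  sprintf("truncated binary STL: %s", path))
  }
  m <- matrix(body, nrow = 50L)
  tri_floats <- apply(m[13:48, , drop = FALSE], 2L, function(b) {
    readBin(b, "numeric", n = 9L, size = 4L, endian = "little")
  })
  # column-major flattening of the 9 x ntri block is already in
  # (x1 y1 z1 x2 ... z3) vertex order per facet
  coords <- matrix(as.numeric(tri_floats), ncol = 3L, byrow = TRUE)
  list(vertices = coords,
       faces = matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
             u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
             u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
  out <- c(sprintf("solid %s", gsub("\\s+", "_", mesh$name)),
           paste0("  facet normal ", fmt(n), "\n",
                  "    outer loop\n",
                  "      vertex ", fmt(a), "\n",
                  "      vertex ", fmt(b), "\n",
                  "      vertex ", fmt(c_), "\n",
                  "    endloop\n",
                  "  endfacet"),
           sprintf("endsolid %s", gsub("\\s+", "_", mesh$name)))
  writeLines(out, path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", paste("binary stl", mesh$name)))[1:80]
  writeBin(header, con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]
    b <- v[f[i, 2L], ]
    cc <- v[f[i, 3L], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

# -- PLY (ASCII) -------------------------------------------------------------

read_ply_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply") {
    stop_quadzone("quadzone_format_error", sprintf("not a PLY file: %s", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("PLY header not terminated in %s", path))
  }
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format\\s+binary", header))) {
    stop_quadzone("quadzone_format_error",
                  "binary PLY is not supported; export ASCII PLY")
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex\\s", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face\\s", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("PLY vertex/face counts missing in %s", path))
  }
  body <- lines[(end + 1L):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  # vertex properties appear before the face element in a well-formed header
  vert_block <- header[seq(grep("^element vertex", header)[1L],
                           grep("^element face", header)[1L] - 1L)]
  vnames <- sub(".*\\s", "", grep("^property\\s", vert_block, value = TRUE))
  vals <- matrix(as.numeric(unlist(vtok)), nrow = nv, byrow = TRUE)
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) {
    stop_quadzone("quadzone_format_error", "PLY vertex x/y/z properties missing")
  }
  vertices <- vals[, xyz, drop = FALSE]
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(ftok, function(tk) {
    n <- as.integer(tk[1L])
    if (n != 3L) {
      stop_quadzone("quadzone_format_error", "only triangular PLY faces supported")
    }
    as.integer(tk[2:4]) + 1L
  }, integer(3L)))
  extra <- setdiff(vnames, c("x", "y", "z"))
  props <- if (length(extra)) {
    as.data.frame(vals[, match(extra, vnames), drop = FALSE]) |>
      stats::setNames(extra)
  } else NULL
  list(vertices = vertices, faces = faces, vertex_props = props)
}

#' Write a mesh as ASCII PLY, optionally with per-vertex zone labels
#'
#' Zone overlays use the integer convention 0 = absolute safe,
#' 1 = relatively dangerous, 2 = absolute dangerous.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param vertex_labels optional integer vector, one value per vertex,
#'   written as a per-vertex `zone` property.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, vertex_labels = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  has_zone <- !is.null(vertex_labels)
  if (has_zone && length(vertex_labels) != nrow(v)) {
    stop_quadzone("quadzone_invalid_argument",
                  "vertex_labels must have one value per vertex")
  }
  header <- c("ply", "format ascii 1.0",
              sprintf("comment %s", mesh$name),
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              if (has_zone) "property int zone",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- if (has_zone) {
    sprintf("%.9g %.9g %.9g %d", v[, 1L], v[, 2L], v[, 3L],
            as.integer(vertex_labels))
  } else {
    sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L])
  }
  flines <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

# -- OBJ ---------------------------------------------------------------------

read_obj_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("no OBJ geometry found in %s", path))
  }
  vt <- strsplit(trimws(sub("^v\\s+", "", vl)), "\\s+")
  vertices <- matrix(as.numeric(unlist(lapply(vt, `[`, 1:3))),
                     ncol = 3L, byrow = TRUE)
  ft <- strsplit(trimws(sub("^f\\s+", "", fl)), "\\s+")
  faces <- t(vapply(ft, function(tk) {
    if (length(tk) != 3L) {
      stop_quadzone("quadzone_format_error", "only triangular OBJ faces supported")
    }
    as.integer(sub("/.*$", "", tk))
  }, integer(3L)))
  if (anyNA(vertices) || anyNA(faces)) {
    stop_quadzone("quadzone_format_error",
                  sprintf("malformed OBJ data in %s", path))
  }
  list(vertices = vertices, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("o %s", gsub("\\s+", "_", mesh$name)),
               sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])), path)
  invisible(path)
}
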