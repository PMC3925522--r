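test_that("mesh construction validates and welds", {
  expect_error(triangle_mesh(matrix(numeric(0), ncol = 3),
                             matrix(integer(0), ncol = 3)),
               class = "quadzone_degenerate_input")
  expect_error(triangle_mesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)),
                             rbind(1:3)),
               class = "quadzone_invalid_argument")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1L, 2L, 5L))),
               class = "quadzone_invalid_argument")
  # duplicated vertices merge; degenerate face is dropped
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                     rbind(c(1L, 2L, 3L), c(4L, 5L, 6L), c(1L, 4L, 2L)))
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 2L)
})

test_that("watertightness detects closed and open surfaces", {
  expect_true(is_watertight(tetra_mesh()))
  expect_true(is_watertight(sphere_mesh()))
  open_patch <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                              rbind(1:3))
  expect_false(is_watertight(open_patch))
})

test_that("STL round trips preserve geometry in both dialects", {
  m <- tetra_mesh()
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_mesh(m, path, binary = binary)
    m2 <- load_mesh(path)
    expect_equal(n_vertices(m2), 4L)
    expect_equal(n_faces(m2), 4L)
    # welded STL facets reproduce the unique coordinate set
    expect_equal(
      m2$vertices[order(m2$vertices[, 1], m2$vertices[, 2], m2$vertices[, 3]), ],
      m$vertices[order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), ],
      tolerance = 1e-6)
    expect_true(is_watertight(m2))
  }
})

test_that("STL welding matches brute-force unique coordinate count", {
  m <- sphere_mesh(radius = 7, n_lat = 6L, n_lon = 9L)
  path <- tempfile(fileext = ".stl")
  write_mesh(m, path)
  # the ASCII STL stores 3 vertices per facet; welding must recover the
  # number of distinct coordinate triples
  lines <- grep("vertex", readLines(path), value = TRUE)
  uniq <- length(unique(trimws(lines)))
  m2 <- load_mesh(path)
  expect_equal(n_vertices(m2), uniq)
  expect_equal(n_faces(m2), n_faces(m))
})

test_that("PLY and OBJ round trips work, PLY carries zone labels", {
  m <- tetra_mesh()
  ply <- tempfile(fileext = ".ply")
  write_mesh(m, ply, vertex_labels = c(0L, 1L, 2L, 1L))
  m2 <- load_mesh(ply)
  expect_equal(n_vertices(m2), 4L)
  expect_equal(n_faces(m2), 4L)
  raw <- quadzone:::read_ply_raw(ply)
  expect_equal(raw$vertex_props$zone, c(0, 1, 2, 1))
  obj <- tempfile(fileext = ".obj")
  write_mesh(m, obj)
  m3 <- load_mesh(obj)
  expect_equal(n_vertices(m3), 4L)
  expect_equal(n_faces(m3), 4L)
})

test_that("unparsable and empty files raise format errors", {
  bad <- tempfile(fileext = ".stl")
  writeLines(c("solid junk", "endsolid junk"), bad)
  expect_error(load_mesh(bad), class = "quadzone_format_error")
  expect_error(load_mesh(tempfile(fileext = ".stl")),
               class = "quadzone_format_error")
  expect_error(load_mesh(tempfile(fileext = ".xyz")),
               class = "quadzone_format_error")
})

test_that("generated phantom inner surface exports watertight STL", {
  sp <- phantom_spec(mesh_resolution = 3, entry_spacing = 4)
  ph <- generate_phantom(sp)
  path <- tempfile(fileext = ".stl")
  write_mesh(ph$inner_surface, path)
  m <- load_mesh(path)
  expect_true(is_watertight(m))
  expect_equal(n_faces(m), n_faces(ph$inner_surface))
})

test_that("ray_intersections matches analytic sphere hits", {
  m <- sphere_mesh(center = c(30, 0, 0), radius = 10, n_lat = 24L,
                   n_lon = 36L)
  # generic ray close to the centre line (avoids shared mesh vertices,
  # where exhaustive intersection correctly reports every incident face)
  o <- c(0, 0.37, 0.21)
  hits <- ray_intersections(m, o, c(1, 0, 0))
  expect_equal(nrow(hits), 2L)
  b2 <- 0.37^2 + 0.21^2
  expect_equal(hits$t, 30 + c(-1, 1) * sqrt(100 - b2), tolerance = 0.05)
  # pointing away
  expect_equal(nrow(ray_intersections(m, c(0, 0, 0), c(-1, 0, 0))), 0L)
  # tangent line offset outside the sphere by more than an edge length
  expect_equal(nrow(ray_intersections(m, c(0, 0, 12.5), c(1, 0, 0))), 0L)
  expect_error(ray_intersections(m, c(0, 0, 0), c(0, 0, 0)),
               class = "quadzone_invalid_argument")
})

test_that("ray_intersections agrees with the brute-force oracle", {
  m <- sphere_mesh(radius = 9, n_lat = 12L, n_lon = 18L)  # < 500 faces
  expect_lte(n_faces(m), 500L)
  set.seed(7)
  for (i in 1:250) {
    o <- runif(3, -25, 25)
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    got <- ray_intersections(m, o, d)$t
    want <- oracle_ray_hits(m, o, d)
    expect_equal(length(got), length(want))
    if (length(got)) expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("distance_to_surface matches analytic and brute-force values", {
  m <- sphere_mesh(radius = 10, n_lat = 30L, n_lon = 45L)
  # centre of the sphere: distance = radius (to the inscribed facets)
  expect_equal(distance_to_surface(m, c(0, 0, 0)), 10, tolerance = 0.05)
  # a vertex lies on the surface
  expect_equal(distance_to_surface(m, m$vertices[5L, ]), 0)
  # signed distance flips sign inside
  expect_lt(distance_to_surface(m, c(0, 0, 0), signed = TRUE), 0)
  expect_gt(distance_to_surface(m, c(0, 0, 15), signed = TRUE), 0)
  # point above a flat plate
  plate <- triangle_mesh(rbind(c(-50, -50, 0), c(50, -50, 0),
                               c(50, 50, 0), c(-50, 50, 0)),
                         rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(distance_to_surface(plate, c(3, 4, 5)), 5, tolerance = 1e-12)
  # brute-force agreement
  small <- sphere_mesh(radius = 6, n_lat = 10L, n_lon = 15L)
  expect_lte(n_faces(small), 500L)
  set.seed(11)
  pts <- matrix(runif(150, -12, 12), ncol = 3L)
  got <- distance_to_surface(small, pts)
  want <- vapply(seq_len(nrow(pts)), function(i)
    oracle_mesh_distance(small, pts[i, ]), numeric(1L))
  expect_equal(got, want, tolerance = 1e-9)
})
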