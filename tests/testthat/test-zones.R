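grid_50 <- function(half = 25, n = 50L) {
  xs <- seq(-half, half, length.out = n)
  cbind(rep(xs, times = n), rep(xs, each = n), 0)
}

test_that("occluded_mask matches simple shadow intuition", {
  occ <- sphere_mesh(center = c(0, 0, 15), radius = 6, n_lat = 16L,
                     n_lon = 24L)
  vp <- c(0, 0, 40)
  # directly below the sphere: hidden; far to the side: visible
  m <- occluded_mask(rbind(c(0, 0, 0), c(24, 0, 0)), occ, vp)
  expect_identical(m, c(TRUE, FALSE))
  expect_error(occluded_mask(rbind(vp), occ, vp),
               class = "quadzone_invalid_argument")
})

test_that("occluded_mask equals brute-force segment testing and the shadow conic", {
  occ <- sphere_mesh(center = c(0, 3, 15), radius = 6, n_lat = 16L,
                     n_lon = 24L)
  vp <- c(5, -8, 40)
  pts <- grid_50()
  got <- occluded_mask(pts, occ, vp)
  # (i) exact agreement with per-triangle brute force
  want <- oracle_segment_occluded(occ, vp, pts)
  expect_identical(got, want)
  # (ii) agreement with the analytic sphere shadow away from the boundary
  margin <- oracle_segment_sphere_margin(pts, vp, c(0, 3, 15), 6)
  analytic <- oracle_sphere_occluded(pts, vp, c(0, 3, 15), 6)
  edge <- mean_edge_length(occ)
  off_boundary <- margin > edge
  expect_identical(got[off_boundary], analytic[off_boundary])
})

test_that("grid-accelerated occlusion equals the scanning path exactly", {
  occ <- sphere_mesh(center = c(2, -1, 12), radius = 7, n_lat = 50L,
                     n_lon = 80L)
  expect_gte(n_faces(occ), 4000L)
  set.seed(3)
  pts <- cbind(runif(600, -25, 25), runif(600, -25, 25), 0)
  vps <- rbind(c(0, 0, 40), c(-20, 10, 35), c(15, 25, 30))
  g <- quadzone:::cpp_occlusion_matrix(occ$vertices, occ$faces, pts, vps,
                                       1e-6, 1L)         # force grid
  b <- quadzone:::cpp_occlusion_matrix(occ$vertices, occ$faces, pts, vps,
                                       1e-6, .Machine$integer.max)  # brute
  expect_identical(g, b)
})

test_that("no occluder in the way labels everything ABS_SAFE", {
  far <- sphere_mesh(center = c(500, 500, 500), radius = 2, n_lat = 6L,
                     n_lon = 9L)
  ap <- make_incision(c(0, -10, 40), c(0, 10, 40), 5L)
  zm <- classify_zones(grid_50(10, 10L), far, far, ap)
  expect_true(all(zm$labels == "ABS_SAFE"))
  expect_error(extract_landmarks(zm, rbind(c(-10, 20, 0), c(10, 20, 0)),
                                 c(0, -5, 0)),
               class = "quadzone_no_landmarks")
})

test_that("single-viewpoint zones reproduce the analytic shadow rings", {
  ctr <- c(0, 5, 12)
  sh_abs <- sphere_mesh(center = ctr, radius = 3, n_lat = 20L, n_lon = 30L)
  sh_mar <- sphere_mesh(center = ctr, radius = 5, n_lat = 20L, n_lon = 30L)
  ap <- make_incision(c(0, 0, 40), c(0, 1e-3, 40), 2L)  # near-degenerate
  pts <- grid_50()
  zm <- classify_zones(pts, sh_abs, sh_mar, ap)
  vp <- c(0, 0, 40)
  in_abs <- oracle_sphere_occluded(pts, vp, ctr, 3)
  in_mar <- oracle_sphere_occluded(pts, vp, ctr, 5)
  edge <- mean_edge_length(sh_mar)
  off <- oracle_segment_sphere_margin(pts, vp, ctr, 3) > edge &
    oracle_segment_sphere_margin(pts, vp, ctr, 5) > edge
  expect_identical((zm$labels == "ABS_DANGER")[off], in_abs[off])
  expect_identical((zm$labels == "ABS_SAFE")[off], !in_mar[off])
  expect_identical((zm$labels == "REL_DANGER")[off], (in_mar & !in_abs)[off])
})

test_that("two-viewpoint zones follow shadow set algebra", {
  ctr <- c(0, 5, 12)
  sh_abs <- sphere_mesh(center = ctr, radius = 3, n_lat = 20L, n_lon = 30L)
  sh_mar <- sphere_mesh(center = ctr, radius = 5, n_lat = 20L, n_lon = 30L)
  v1 <- c(-15, 0, 40)
  v2 <- c(15, 0, 40)
  ap <- make_incision(v1, v2, 2L)
  pts <- grid_50()
  zm <- classify_zones(pts, sh_abs, sh_mar, ap)
  danger_want <- oracle_sphere_occluded(pts, v1, ctr, 3) &
    oracle_sphere_occluded(pts, v2, ctr, 3)
  safe_want <- !oracle_sphere_occluded(pts, v1, ctr, 5) |
    !oracle_sphere_occluded(pts, v2, ctr, 5)
  edge <- mean_edge_length(sh_mar)
  off <- pmin(oracle_segment_sphere_margin(pts, v1, ctr, 3),
              oracle_segment_sphere_margin(pts, v2, ctr, 3)) > edge &
    pmin(oracle_segment_sphere_margin(pts, v1, ctr, 5),
         oracle_segment_sphere_margin(pts, v2, ctr, 5)) > edge
  expect_identical((zm$labels == "ABS_DANGER")[off], danger_want[off])
  expect_identical((zm$labels == "ABS_SAFE")[off], safe_want[off])
})

test_that("shell nesting implies per-viewpoint occlusion nesting", {
  ctr <- c(0, 5, 12)
  sh_abs <- sphere_mesh(center = ctr, radius = 3, n_lat = 20L, n_lon = 30L)
  sh_mar <- sphere_mesh(center = ctr, radius = 5, n_lat = 20L, n_lon = 30L)
  ap <- make_incision(c(-15, 0, 40), c(15, 0, 40), 7L)
  zm <- classify_zones(grid_50(), sh_abs, sh_mar, ap)
  expect_true(all(zm$occluded_margin[zm$occluded_absolute]))
  # vertices occluded by the absolute shell from all viewpoints can never
  # be labelled safe
  danger_all <- rowSums(zm$occluded_absolute) == ncol(zm$occluded_absolute)
  expect_true(all(zm$labels[danger_all] == "ABS_DANGER"))
})

test_that("adding viewpoints shrinks danger and grows safety", {
  ctr <- c(0, 5, 12)
  sh_abs <- sphere_mesh(center = ctr, radius = 3, n_lat = 16L, n_lon = 24L)
  sh_mar <- sphere_mesh(center = ctr, radius = 5, n_lat = 16L, n_lon = 24L)
  pts <- grid_50()
  z1 <- classify_zones(pts, sh_abs, sh_mar,
                       make_incision(c(-15, 0, 40), c(15, 0, 40), 6L))
  z2 <- classify_zones(pts, sh_abs, sh_mar,
                       make_incision(c(-15, 0, 40), c(15, 0, 40), 11L))
  expect_true(all(z1$labels[z2$labels == "ABS_DANGER"] == "ABS_DANGER"))
  expect_true(all(z2$labels[z1$labels == "ABS_SAFE"] == "ABS_SAFE"))
})

test_that("the union quantifier flips the zone containments", {
  ctr <- c(0, 5, 12)
  sh_abs <- sphere_mesh(center = ctr, radius = 3, n_lat = 16L, n_lon = 24L)
  sh_mar <- sphere_mesh(center = ctr, radius = 5, n_lat = 16L, n_lon = 24L)
  ap <- make_incision(c(-15, 0, 40), c(15, 0, 40), 7L)
  pts <- grid_50()
  zi <- classify_zones(pts, sh_abs, sh_mar, ap, quantifier = "intersection")
  zu <- classify_zones(pts, sh_abs, sh_mar, ap, quantifier = "union")
  expect_true(all(zu$labels[zi$labels == "ABS_DANGER"] == "ABS_DANGER"))
  expect_true(all(zi$labels[zu$labels == "ABS_SAFE"] == "ABS_SAFE"))
  expect_gte(sum(zu$labels == "ABS_DANGER"), sum(zi$labels == "ABS_DANGER"))
})
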