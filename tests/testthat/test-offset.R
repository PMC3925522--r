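test_that("absolute clearance is the subchondral thickness plus screw radius", {
  expect_identical(compute_absolute_clearance(1.2, 1.75), 2.95)
  expect_identical(compute_absolute_clearance(0, 0), 0)
  expect_identical(compute_absolute_clearance(0.5, 1.75), 2.25)
  expect_error(compute_absolute_clearance(-0.1, 1.75),
               class = "quadzone_invalid_argument")
})

test_that("offset_spec enforces its invariants", {
  os <- offset_spec()
  expect_equal(os$d_absolute, 2.95)
  expect_equal(os$d_with_margin, 6)
  expect_gte(os$d_with_margin, os$d_absolute)
  expect_error(offset_spec(d_with_margin = 2),
               class = "quadzone_invalid_argument")
  expect_error(offset_spec(screw_radius_min = -1),
               class = "quadzone_invalid_argument")
})

test_that("sphere offsets land at the analytic radii", {
  m <- sphere_mesh(radius = 24, n_lat = 36L, n_lon = 54L)
  pitch <- 0.5
  # identity offset
  m0 <- offset_surface(m, 0, voxel_pitch = pitch)
  r0 <- sqrt(rowSums(m0$vertices^2))
  expect_true(all(abs(r0 - 24) < 2 * pitch))
  for (d in c(2.95, 6)) {
    sh <- offset_surface(m, d, voxel_pitch = pitch)
    r <- sqrt(rowSums(sh$vertices^2))
    # closed input: iso-surface has an outer shell at 24 + d and an inner
    # shell at 24 - d
    outer <- r[r > 24]
    inner <- r[r < 24]
    expect_gt(length(outer), 0L)
    expect_true(all(abs(outer - (24 + d)) < 2 * pitch))
    if (length(inner)) expect_true(all(abs(inner - (24 - d)) < 2 * pitch))
    expect_true(is_watertight(sh))
  }
})

test_that("offsets nest: the smaller shell lies inside the larger", {
  m <- sphere_mesh(radius = 24, n_lat = 28L, n_lon = 42L)
  s1 <- offset_surface(m, 2.95, voxel_pitch = 0.6)
  s2 <- offset_surface(m, 6, voxel_pitch = 0.6)
  idx <- round(seq(1, n_vertices(s1), length.out = 400L))
  pts <- s1$vertices[idx, ]
  sd <- distance_to_surface(s2, pts, signed = TRUE)
  expect_true(all(sd <= 1e-6))
})

test_that("sampled offset points lie at distance d from the source", {
  cap <- generate_phantom(phantom_spec(mesh_resolution = 2,
                                       entry_spacing = 4))$acetabular_cap
  d <- 2.95
  pitch <- 0.5
  sh <- offset_surface(cap, d, voxel_pitch = pitch)
  idx <- round(seq(1, n_vertices(sh), length.out = 1000L))
  dist <- distance_to_surface(cap, sh$vertices[idx, ])
  expect_true(all(dist >= d - 2 * pitch & dist <= d + 2 * pitch))
  # tighter in the bulk: the median deviation is far below the pitch
  expect_lt(median(abs(dist - d)), 0.1)
})

test_that("open hemispherical cap offsets to radius + d on the dome", {
  sp <- phantom_spec(mesh_resolution = 2, entry_spacing = 4)
  cap <- generate_phantom(sp)$acetabular_cap
  ctr <- sp$acetabulum_center
  r <- sp$acetabulum_radius
  d <- 6
  sh <- offset_surface(cap, d, voxel_pitch = 0.5)
  v <- sh$vertices
  rel <- sweep(v, 2, ctr)
  rad <- sqrt(rowSums(rel^2))
  ang <- acos(pmin(1, pmax(-1, rel[, 3] / rad))) * 180 / pi
  dome <- ang < sp$cup_half_angle_deg - 15 & rad > r
  expect_gt(sum(dome), 100L)
  expect_true(all(abs(rad[dome] - (r + d)) < 1))
})

test_that("invalid offsets are refused", {
  m <- sphere_mesh(radius = 10, n_lat = 10L, n_lon = 15L)
  expect_error(offset_surface(m, -1), class = "quadzone_invalid_argument")
  expect_warning(
    expect_error(offset_surface(m, 0.4, voxel_pitch = 0.5),
                 class = "quadzone_invalid_argument"),
    "coarser")
})
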