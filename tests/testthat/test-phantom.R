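coarse_spec <- function(...) {
  phantom_spec(mesh_resolution = 3, entry_spacing = 4, ...)
}

test_that("phantom generation is deterministic", {
  a <- generate_phantom(coarse_spec())
  b <- generate_phantom(coarse_spec())
  expect_identical(a$inner_surface$vertices, b$inner_surface$vertices)
  expect_identical(a$acetabular_cap$vertices, b$acetabular_cap$vertices)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$entry_points, b$entry_points)
})

test_that("the articular cap is exactly spherical and the slab watertight", {
  sp <- coarse_spec()
  ph <- generate_phantom(sp)
  rad <- sqrt(rowSums(sweep(ph$acetabular_cap$vertices, 2,
                            sp$acetabulum_center)^2))
  expect_true(all(abs(rad - sp$acetabulum_radius) < 1e-9))
  expect_true(is_watertight(ph$inner_surface))
  expect_false(is_watertight(ph$acetabular_cap))
  # entry points lie in the region
  expect_true(all(ph$region_filter(ph$entry_points)))
})

test_that("infeasible specs raise spec errors", {
  expect_error(phantom_spec(foramen_center = c(40, -20)),
               class = "quadzone_spec_error")
  expect_error(phantom_spec(cup_clearance = -1),
               class = "quadzone_spec_error")
  expect_error(phantom_spec(cup_clearance = 20),
               class = "quadzone_spec_error")
  expect_error(phantom_spec(scale = 0), class = "quadzone_spec_error")
})

test_that("analytic occlusion matches the orthographic limit far away", {
  sp <- coarse_spec()
  tr <- analytic_truth(sp, offsets = c(2.95, 6))
  d <- 6
  R <- sp$acetabulum_radius + d
  depth <- -sp$acetabulum_center[3L]
  # viewed from far along the plate normal, the shadow on the plate is
  # the disk where the offset sphere crosses the plane
  rad <- sqrt(R^2 - depth^2)
  vp_far <- c(sp$cup_center_xy, 1e6)
  th <- seq(0, 2 * pi, length.out = 41L)
  inside <- cbind(sp$cup_center_xy[1L] + 0.99 * rad * cos(th),
                  sp$cup_center_xy[2L] + 0.99 * rad * sin(th), 0)
  outside <- cbind(sp$cup_center_xy[1L] + 1.01 * rad * cos(th),
                   sp$cup_center_xy[2L] + 1.01 * rad * sin(th), 0)
  expect_true(all(tr$occluded(inside, vp_far, d)))
  expect_false(any(tr$occluded(outside, vp_far, d)))
})

test_that("truth is undefined for viewpoints inside the shell or noisy cups", {
  sp <- coarse_spec()
  bad_ap <- make_incision(sp$acetabulum_center + c(0, 0, 26),
                          sp$acetabulum_center + c(0, 1, 26), 2L)
  expect_error(analytic_truth(sp, offsets = 6, aperture = bad_ap),
               class = "quadzone_truth_undefined")
  expect_error(analytic_truth(coarse_spec(noise_sigma = 0.2)),
               class = "quadzone_truth_undefined")
  expect_error(analytic_truth(coarse_spec(lumpy = TRUE)),
               class = "quadzone_truth_undefined")
})

test_that("mesh occlusion agrees with the analytic sphere predicate", {
  # validates that every admissible sight line interacts with the shell
  # only on its cap-offset side, where shell and offset sphere coincide
  sp <- coarse_spec()
  ph <- generate_phantom(sp)
  tr <- analytic_truth(sp)
  d <- 2.95
  sh <- offset_surface(ph$acetabular_cap, d, voxel_pitch = 0.5)
  vp <- sp$incision_proximal
  pts <- ph$entry_points
  got <- occluded_mask(pts, sh, vp)
  want <- as.logical(tr$occluded(pts, vp, d))
  margin <- oracle_segment_sphere_margin(pts, vp, sp$acetabulum_center,
                                         sp$acetabulum_radius + d)
  off <- margin > 0.25
  expect_identical(got[off], want[off])
})

test_that("cohorts are reproducible, feasible and bounded", {
  base <- coarse_spec()
  c1 <- generate_cohort(base, 1L, variation = 0)
  expect_equal(c1[[1L]]$acetabulum_radius, base$acetabulum_radius)
  c20a <- generate_cohort(base, 20L, variation = 0.05, seed = 7L)
  c20b <- generate_cohort(base, 20L, variation = 0.05, seed = 7L)
  expect_identical(c20a, c20b)
  radii <- vapply(c20a, `[[`, numeric(1L), "acetabulum_radius")
  expect_gt(sd(radii), 0)
  expect_error(generate_cohort(base, 5L, variation = 5, seed = 1L),
               class = "quadzone_cohort_error")
  expect_error(generate_cohort(base, 0L), class = "quadzone_cohort_error")
})

test_that("zero-variation cohorts collapse to mean = min = max", {
  base <- coarse_spec()
  specs <- generate_cohort(base, 4L, variation = 0)
  recs <- unlist(lapply(specs, function(s) {
    tr <- analytic_truth(s, offsets = c(2.95, 6))
    lapply(tr$per_offset, `[[`, "record")
  }), recursive = FALSE)
  s <- aggregate_cohort(recs)
  expect_true(all(abs(s$stats$mean - s$stats$min) < 1e-9))
  expect_true(all(abs(s$stats$max - s$stats$min) < 1e-9))
})

test_that("uniformly scaled anatomy scales every measurement", {
  s <- 1.5
  tr1 <- analytic_truth(phantom_spec(), offsets = c(2.95, 6))
  tr2 <- analytic_truth(phantom_spec(scale = s), offsets = c(2.95, 6) * s)
  for (i in 1:2) {
    r1 <- tr1$per_offset[[i]]$record
    r2 <- tr2$per_offset[[i]]$record
    for (m in c("EK", "FK", "GM", "GN", "HP", "HQ")) {
      expect_equal(r2[[m]], s * r1[[m]], tolerance = 0.02)
    }
  }
})
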