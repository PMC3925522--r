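flat_frame <- function() {
  set.seed(1)
  pts <- cbind(runif(60, -30, 30), runif(60, -30, 30), 0)
  brim <- cbind(seq(-30, 30, by = 1), 20, 0)
  fit_reference_frame(pts, brim)
}

test_that("reference frame recovers the plane and brim direction", {
  fr <- flat_frame()
  expect_equal(abs(fr$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(abs(fr$tangent), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(sum(fr$tangent * fr$normal), 0, tolerance = 1e-12)
  # noisy plane: normal within 1 degree
  set.seed(2)
  pts <- cbind(runif(400, -30, 30), runif(400, -30, 30), rnorm(400, 0, 0.1))
  fr2 <- fit_reference_frame(pts, cbind(seq(-30, 30, 1), 20, 0))
  ang <- acos(abs(sum(fr2$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("degenerate frames are rejected", {
  brim <- cbind(seq(-5, 5, 1), 20, 0)
  expect_error(fit_reference_frame(rbind(c(0, 0, 0), c(1, 0, 0)), brim),
               class = "quadzone_frame_error")
  line_pts <- cbind(seq(0, 10, length.out = 20), 0, 0)
  expect_error(fit_reference_frame(line_pts, brim),
               class = "quadzone_frame_error")
})

test_that("perpendicular feet match orthogonal projection and endpoints", {
  fr <- flat_frame()
  brim <- cbind(seq(-10, 10, by = 0.5), 0, 0)
  expect_equal(foot_of_perpendicular(c(5, 3, 0), brim, fr), c(5, 0, 0),
               tolerance = 1e-9)
  # beyond the parameter range: nearest endpoint
  expect_equal(foot_of_perpendicular(c(25, 3, 0), brim, fr), c(10, 0, 0),
               tolerance = 1e-9)
})

test_that("feet on an arc equal brute-force minimisation over dense samples", {
  fr <- flat_frame()
  th <- seq(-0.6, 0.6, length.out = 200L)
  arc <- cbind(50 * sin(th), 50 * cos(th) - 50 + 10, 0)  # radius 50 arc
  dense <- quadzone:::densify_polyline(arc, 0.02)
  set.seed(5)
  for (i in 1:20) {
    p <- c(runif(1, -20, 20), runif(1, -35, 5), 0)
    foot <- foot_of_perpendicular(p, arc, fr)
    d2 <- sqrt(rowSums((dense - matrix(p, nrow(dense), 3L, byrow = TRUE))^2))
    brute <- dense[which.min(d2), ]
    expect_lt(sqrt(sum((foot - brute)^2)), 0.025)
  }
})

test_that("brim-parallel lines intersect target polylines analytically", {
  fr <- flat_frame()
  th <- seq(0, 2 * pi, length.out = 721L)
  circle <- cbind(20 + 5 * cos(th), 10 + 5 * sin(th), 0)
  got <- line_parallel_intersection(c(0, 10, 0), c(1, 0, 0), circle, fr)
  expect_equal(got, c(15, 10, 0), tolerance = 1e-3)
  # a point on the polyline maps to itself
  on_poly <- line_parallel_intersection(c(25, 10, 0), c(1, 0, 0), circle, fr)
  expect_equal(on_poly, c(25, 10, 0), tolerance = 1e-3)
  # parallel line missing the target
  seg <- rbind(c(-5, 30, 0), c(5, 30, 0))
  expect_error(line_parallel_intersection(c(0, 10, 0), c(1, 0, 0), seg, fr),
               class = "quadzone_no_intersection")
})

make_flat_case <- function() {
  # straight brim y = 20, circular foramen centre (0, -10) radius 8,
  # hand-placed landmarks with closed-form constructions
  brim <- cbind(seq(-30, 30, by = 0.25), 20, 0)
  th <- seq(0, 2 * pi, length.out = 2001L)
  rim <- cbind(8 * sin(th), -10 + 8 * cos(th), 0)
  lms <- structure(list(E = c(-12, 20, 0), F = c(6, 20, 0),
                        G = c(-9, -6, 0), H = c(-2, -4, 0),
                        shell = "absolute"), class = "zone_landmarks")
  set.seed(4)
  pts <- cbind(runif(80, -30, 30), runif(80, -30, 30), 0)
  frame <- fit_reference_frame(pts, brim)
  list(brim = brim, rim = rim, lms = lms, frame = frame,
       foramen_top = c(0, -2, 0))
}

test_that("measurements match closed-form coordinate geometry", {
  cs <- make_flat_case()
  rec <- measure_record(cs$lms, cs$brim, cs$rim, cs$foramen_top, cs$frame,
                        offset_d = 2.95)
  # K = foot of (0,-2) on the line y = 20 -> (0, 20); distances in cm.
  expect_equal(rec$EK, 1.2, tolerance = 1e-4)    # |(-12,20) - (0,20)|
  expect_equal(rec$FK, 0.6, tolerance = 1e-4)    # |(6,20) - (0,20)|
  expect_equal(rec$GM, 2.6, tolerance = 1e-4)    # G=(-9,-6) to (-9,20)
  # N: horizontal line through G at y = -6 meets the circle
  # (x, -10) + 8: x = +-sqrt(64 - 16); nearest to -9 is -sqrt(48)
  expect_equal(rec$GN, (9 - sqrt(48)) / 10, tolerance = 1e-3)
  expect_equal(rec$HP, 2.4, tolerance = 1e-4)    # H=(-2,-4) to (-2,20)
  # Q: y = -4 chord: x = +-sqrt(64 - 36); nearest to -2 is -sqrt(28)
  expect_equal(rec$HQ, (sqrt(28) - 2) / 10, tolerance = 1e-3)
})

test_that("degenerate placements give zero-length segments", {
  cs <- make_flat_case()
  # brim lowered to y = -4 so that a point on the brim still has a
  # brim-parallel line crossing the foramen circle
  brim <- cbind(seq(-30, 30, by = 0.25), -4, 0)
  lms <- cs$lms
  lms$G <- c(-20, -4, 0)  # on the brim: GM = 0
  lms$E <- c(0, -4, 0)    # equal to K (foot of (0,-2)): EK = 0
  lms$H <- c(-2, -6, 0)
  rec <- measure_record(lms, brim, cs$rim, cs$foramen_top, cs$frame)
  expect_equal(rec$GM, 0, tolerance = 1e-9)
  expect_equal(rec$EK, 0, tolerance = 1e-6)
})

test_that("rigid motions leave all measured distances unchanged", {
  cs <- make_flat_case()
  rec0 <- measure_record(cs$lms, cs$brim, cs$rim, cs$foramen_top, cs$frame)
  # random rotation (QR of a fixed random matrix) + translation
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  tr <- c(13.2, -7.5, 40)
  move <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    sweep(p %*% t(Q), 2L, -tr)
  }
  lms2 <- cs$lms
  for (nm in c("E", "F", "G", "H")) lms2[[nm]] <- as.numeric(move(cs$lms[[nm]]))
  set.seed(4)
  pts <- cbind(runif(80, -30, 30), runif(80, -30, 30), 0)
  frame2 <- fit_reference_frame(move(pts), move(cs$brim))
  rec2 <- measure_record(lms2, move(cs$brim), move(cs$rim),
                         as.numeric(move(cs$foramen_top)), frame2)
  for (m in c("EK", "FK", "GM", "GN", "HP", "HQ")) {
    expect_equal(rec2[[m]], rec0[[m]], tolerance = 1e-9)
  }
})

test_that("cohort aggregation formats mean (min-max) in cm", {
  mk <- function(val, id, d = 2.95) {
    structure(list(subject_id = id, offset_d = d,
                   EK = val, FK = val, GM = val, GN = val, HP = val,
                   HQ = val, points = list()),
              class = "measurement_record")
  }
  s <- aggregate_cohort(list(mk(2.58, "a"), mk(2.90, "b"), mk(3.22, "c")))
  expect_equal(s$table$EK[1L], "2.90 (2.58–3.22)")
  expect_true(all(s$stats$min <= s$stats$mean & s$stats$mean <= s$stats$max))
  expect_true(all(s$stats$n == 3L))
  s1 <- aggregate_cohort(list(mk(1.74, "a")))
  expect_equal(s1$table$GN[1L], "1.74 (1.74–1.74)")
  expect_error(aggregate_cohort(list()), class = "quadzone_empty_summary")
})
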