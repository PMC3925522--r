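test_that("viewpoints are uniform with endpoints included", {
  ap <- make_incision(c(0, 0, 0), c(0, 100, 0), 2L)
  expect_equal(ap$viewpoints, rbind(c(0, 0, 0), c(0, 100, 0)))
  expect_equal(ap$length, 100)
  ap11 <- make_incision(c(0, 0, 0), c(0, 100, 0), 11L)
  expect_equal(ap11$viewpoints[, 2L], seq(0, 100, by = 10))
  expect_equal(ap11$viewpoints[1L, ], ap11$proximal_end)
  expect_equal(ap11$viewpoints[11L, ], ap11$distal_end)
})

test_that("degenerate incisions are rejected", {
  expect_error(make_incision(c(0, 0, 0), c(0, 0, 0), 5L),
               class = "quadzone_degenerate_incision")
  expect_error(make_incision(c(0, 0, 0), c(1, 0, 0), 1L),
               class = "quadzone_invalid_argument")
})

test_that("viewpoint sets refine nestedly (n2 = 2 * (n1 - 1) + 1)", {
  a <- make_incision(c(1, 2, 3), c(4, 8, 9), 11L)
  b <- make_incision(c(1, 2, 3), c(4, 8, 9), 21L)
  # every viewpoint of the coarse set appears in the fine set
  for (i in seq_len(11L)) {
    dists <- sqrt(rowSums((b$viewpoints -
      matrix(a$viewpoints[i, ], 21L, 3L, byrow = TRUE))^2))
    expect_lt(min(dists), 1e-9)
  }
})
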