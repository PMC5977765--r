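test_that("neighbor sets have the right size and are symmetric", {
  for (kind in c(4, 8, 6, 26)) {
    c <- connectivity(kind)
    p <- rep(0L, c$dimension)
    nb <- grid_neighbors(p, c)
    expect_equal(nrow(nb), kind)
    expect_equal(nrow(unique(nb)), kind)
    # symmetry: p is a neighbor of each of its neighbors
    for (i in seq_len(nrow(nb))) {
      back <- grid_neighbors(nb[i, ], c)
      expect_true(any(apply(back, 1, function(q) all(q == p))))
    }
  }
  expect_error(connectivity(5), "must be one of")
})

test_that("4/6-connectivity is Manhattan distance 1, 8/26 the unit cube ring", {
  nb4 <- grid_neighbors(c(0L, 0L), connectivity(4))
  expect_true(all(rowSums(abs(nb4)) == 1))
  nb8 <- grid_neighbors(c(0L, 0L), connectivity(8))
  expect_true(all(apply(abs(nb8), 1, max) == 1))
  nb26 <- grid_neighbors(c(0L, 0L, 0L), connectivity(26))
  expect_true(all(apply(abs(nb26), 1, max) == 1))
  expect_equal(nrow(nb26), 26)
})

test_that("discrete measures count points and validate chain structure", {
  seg <- cbind(x = 1:5, y = rep(1L, 5))
  expect_equal(discrete_measure(seg, connectivity(4), role = "open"), 5)
  sq <- as.matrix(expand.grid(x = 1:3, y = 1:3))
  expect_equal(discrete_measure(sq), 9)
  # closed 4-point ring under 8-connectivity
  ring <- cbind(x = c(1L, 0L, -1L, 0L), y = c(0L, 1L, 0L, -1L))
  expect_equal(discrete_measure(ring, connectivity(8), role = "closed"), 4)
  # branching point is rejected and named
  tee <- cbind(x = c(0L, 1L, 2L, 1L), y = c(0L, 0L, 0L, 1L))
  expect_error(discrete_measure(tee, connectivity(4), role = "open"),
               "connective to 3")
})

test_that("surface extraction matches brute-force counts and is idempotent", {
  sq <- as.matrix(expand.grid(x = 1:3, y = 1:3))
  s <- surface_of(sq, connectivity(4))
  expect_equal(nrow(s), 8)  # all but the center
  expect_equal(nrow(surface_of(s, connectivity(4))), 8)  # thin: fixed point
  one <- matrix(c(5L, 5L), 1, 2)
  expect_equal(surface_of(one, connectivity(8)), one)
  cube <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5))
  expect_equal(nrow(surface_of(cube, connectivity(6))), 125 - 27)
})

test_that("regularity_2d matches tabulated discrete-circle values", {
  # decoded (L, S) pairs of the digitized-circle table, radii 1/3/5/10
  expect_equal(round(regularity_2d(8, 9), 3), 1.767)
  expect_equal(round(regularity_2d(4, 5), 3), 3.927)
  expect_equal(round(regularity_2d(24, 45), 3), 0.982)
  expect_equal(round(regularity_2d(16, 37), 3), 1.816)
  expect_equal(round(regularity_2d(40, 97), 3), 0.762)
  expect_equal(round(regularity_2d(28, 96), 3), 1.539)
  expect_equal(round(regularity_2d(80, 349), 3), 0.685)
  expect_equal(round(regularity_2d(56, 348), 3), 1.394)
  # Euclidean circle scores exactly 1 at any radius
  for (r in c(1, 3, 5, 10, 17.3)) {
    expect_equal(regularity_2d(2 * pi * r, pi * r^2), 1)
  }
  expect_error(regularity_2d(0, 5), "positive")
})

test_that("regularity_2d decreases as contours lengthen at fixed area", {
  L <- seq(10, 100, by = 5)
  eta <- regularity_2d(L, 45)
  expect_true(all(diff(eta) < 0))
})

test_that("3D regularity constant and sphere scores behave as documented", {
  expect_equal(round(kappa_3d("paper"), 3), 1.329)
  expect_equal(kappa_3d("sphere-normalized"), 6 * sqrt(pi))
  V <- 4 * pi / 3; S <- 4 * pi
  expect_equal(regularity_3d(V, S, "sphere-normalized"), 1)
  expect_equal(regularity_3d(V, S, "paper"), 1 / 8)
  # scale invariance: gamma is dimensionless
  for (s in c(2, 5)) {
    expect_equal(regularity_3d(V * s^3, S * s^2, "sphere-normalized"), 1)
  }
  expect_error(regularity_3d(-1, 5), "positive")
})

test_that("ellipse metrics reproduce the circle case and the two eta forms", {
  circ <- ellipse_metrics(2, 2)
  expect_equal(circ$L, 4 * pi)
  expect_equal(circ$S, 4 * pi)
  expect_equal(circ$eta, 1)
  expect_equal(circ$eta_consistent, 1)
  e <- ellipse_metrics(2, 1, scale = 0.5)
  expect_equal(e$eta, 4 * sqrt(0.5) * 4 / 13)
  expect_equal(e$eta_consistent, 128 / 169)
  expect_equal(e$D_E, 1)
  expect_warning(sw <- ellipse_metrics(1, 2), "swapping")
  expect_equal(sw$D, 2)
})

test_that("the two ellipse regularity forms agree at d = D and diverge monotonically", {
  ratios <- seq(1, 0.1, by = -0.1)
  gap <- vapply(ratios, function(r) {
    e <- ellipse_metrics(10, 10 * r)
    e$eta - e$eta_consistent
  }, numeric(1))
  expect_equal(gap[1], 0)
  expect_true(all(diff(gap) > 0))  # gap grows as d/D shrinks
})

test_that("rasterized circles reproduce the calibrated contour/area counts", {
  expected <- data.frame(
    radius = rep(c(1, 3, 5, 10), each = 2),
    kind = rep(c(4L, 8L), 4),
    L = c(8, 4, 24, 16, 40, 28, 80, 56)
  )
  for (i in seq_len(nrow(expected))) {
    rc <- rasterize_circle(expected$radius[i], connectivity(expected$kind[i]))
    expect_equal(rc$L, expected$L[i],
                 label = sprintf("L(r=%d, %d-conn)", expected$radius[i],
                                 expected$kind[i]))
  }
  # area against brute-force disk enumeration at the calibrated thresholds
  r3 <- rasterize_circle(3, connectivity(8))
  expect_equal(r3$S, nrow(brute_disk(3^2 + 3 - 1)))
  expect_equal(r3$S, 37)
  r1 <- rasterize_circle(1, connectivity(8))
  expect_equal(r1$S, 5)
  r1_4 <- rasterize_circle(1, connectivity(4))
  expect_equal(r1_4$S, 9)
  expect_equal(rasterize_circle(3, connectivity(4))$S, 45)
  expect_error(rasterize_circle(0.5, connectivity(8)), "at least 1")
})

test_that("digitized-circle regularity trends hold across radii", {
  radii <- c(1, 3, 5, 10)
  eta4 <- vapply(radii, function(r) rasterize_circle(r, connectivity(4))$eta,
                 numeric(1))
  eta8 <- vapply(radii, function(r) rasterize_circle(r, connectivity(8))$eta,
                 numeric(1))
  expect_true(all(diff(eta4) < 0))
  expect_true(all(diff(eta8) < 0))
  expect_true(all(eta8 > eta4))
})
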