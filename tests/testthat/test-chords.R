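test_that("horizontal chords of a square cover every strip at full width", {
  regs <- make_rect_region(10)
  reg <- regs$regions[[1]]
  cs <- horizontal_chords(reg, delta = 2)
  expect_equal(nrow(cs$chords), 5)
  expect_true(all(cs$chords$length == 10))
  # delta wider than the region collapses to one strip with a warning
  expect_warning(one <- horizontal_chords(reg, delta = 15), "single strip")
  expect_equal(nrow(one$chords), 1)
})

test_that("disk chords are symmetric about the equator and maximal there", {
  regs <- make_disk_region(10)
  reg <- regs$regions[[1]]
  cs <- horizontal_chords(reg, delta = 1)
  len <- cs$chords$length
  expect_equal(len, rev(len))
  expect_equal(max(len), len[(length(len) + 1) / 2])
  # brute-force row runs on the same digitization
  rows <- sort(unique(reg$pixels[, "y"]))
  brute <- vapply(rows, function(r) sum(reg$pixels[, "y"] == r), integer(1))
  expect_equal(len, brute)  # disk rows are single runs
})

test_that("non-convex strips yield one chord per maximal run", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:9, 3:5] <- TRUE   # left arm of a U
  mask[3:9, 8:10] <- TRUE  # right arm
  mask[8:9, 3:10] <- TRUE  # base
  regs <- label_regions(mask, min_area = 1)
  reg <- regs$regions[[1]]
  cs <- horizontal_chords(reg, delta = 1)
  top <- cs$chords[cs$chords$row == 3, ]
  expect_equal(nrow(top), 2)
  base <- cs$chords[cs$chords$row == 8, ]
  expect_equal(nrow(base), 1)
  expect_equal(base$length, 8)
})

test_that("vertical chords trace the region's column extents", {
  regs <- make_rect_region(10)
  reg <- regs$regions[[1]]
  cs <- horizontal_chords(reg, delta = 1)
  mid <- cs$chords[5, ]
  h <- vertical_chords(reg, mid$row, mid$x_start, mid$x_end, spacing = 2)
  expect_length(h, 5)
  expect_true(all(h == 10))
  # short chord: single midpoint sample
  h1 <- vertical_chords(reg, mid$row, mid$x_start, mid$x_start + 1,
                        spacing = 5)
  expect_length(h1, 1)
  # disk: vertical extents via brute-force column counting
  dreg <- make_disk_region(10)$regions[[1]]
  dcs <- horizontal_chords(dreg, delta = 1)
  eq <- dcs$chords[which.max(dcs$chords$length), ]
  h2 <- vertical_chords(dreg, eq$row, eq$x_start, eq$x_end, spacing = 1)
  cols <- eq$x_start:eq$x_end
  brute <- vapply(cols, function(x) sum(dreg$pixels[, "x"] == x), integer(1))
  expect_equal(h2, brute)
  expect_equal(max(h2), 21)  # diameter of the digitized r=10 disk
})

test_that("mean estimator is the arithmetic mean", {
  expect_equal(estimate_g_mean(c(4, 6))$g, 5)
  expect_equal(estimate_g_mean(rep(7, 3))$g, 7)
  set.seed(21)
  phi <- sample(1:40, 1000, replace = TRUE)
  expect_equal(estimate_g_mean(phi)$g, sum(phi) / 1000)
  expect_error(estimate_g_mean(numeric(0)), "empty")
})

test_that("modal estimator reproduces hand-executed binning", {
  phi <- c(rep(10, 8), 20, 30)
  fit <- estimate_g_mode(phi, K = 4)
  expect_equal(fit$c, 5)
  expect_equal(fit$counts, c(8L, 1L, 0L, 1L))
  expect_equal(fit$kappa_star, 1L)
  expect_equal(fit$g, 12.5)
  # degenerate: constant sample returns the constant at any K
  const <- estimate_g_mode(rep(7, 12), K = 5)
  expect_equal(const$g, 7)
  expect_equal(const$K, 1L)
})

test_that("tied peaks reduce K down to the mean fallback", {
  # 5 values in each half: every K = 2 split ties, K = 1 yields the mean
  phi <- c(rep(1, 5), rep(11, 5))
  fit <- estimate_g_mode(phi, K = 2)
  expect_equal(fit$K, 1L)
  expect_equal(fit$g, mean(phi))
})

test_that("small samples fall back to the mean estimator", {
  phi <- c(3, 4, 5)
  fit <- estimate_g_mode(phi)
  expect_equal(fit$method, "mean")
  expect_equal(fit$g, 4)
})

test_that("modal estimator agrees exactly with the brute-force oracle", {
  set.seed(314)
  for (i in 1:300) {
    J <- sample(10:60, 1)
    phi <- sample(1:15, J, replace = TRUE)  # integer lengths, frequent ties
    K <- sample(2:min(9, J - 1), 1)
    expect_equal(estimate_g_mode(phi, K = K)$g, oracle_g_mode(phi, K))
  }
})

test_that("disk volumes follow the elliptic-cylinder formula", {
  expect_equal(disk_volume(2, 2, 1), pi)
  expect_equal(disk_volume(10, 20, 2), 100 * pi)
  expect_error(disk_volume(0, 1, 1), "positive")
  # Riemann-sum check: strips of an analytic sphere sum to (pi/6) d^3
  d <- 40
  rows <- seq(-d / 2 + 0.5, d / 2 - 0.5, by = 1)
  chords <- 2 * sqrt((d / 2)^2 - rows^2)
  total <- sum(disk_volume(chords, chords, 1))
  expect_lt(abs(total - pi / 6 * d^3) / (pi / 6 * d^3), 0.01)
})

test_that("square pore volume matches the hand computation", {
  regs <- make_rect_region(10)
  est <- estimate_volumes(regs, delta = 2, method = "mean",
                          frame_area = 400, scale = 1)
  expect_equal(est$per_pore$volume_pix3, 250 * pi)
  expect_equal(est$V_sigma, 250 * pi)
})

test_that("identical pores give zero volume spread and exact conservation", {
  mask <- matrix(FALSE, 30, 30)
  mask[5:10, 5:10] <- TRUE
  mask[18:23, 18:23] <- TRUE
  regs <- label_regions(mask, min_area = 1)
  est <- estimate_volumes(regs, delta = 1, method = "mean",
                          frame_area = 900, scale = 1)
  expect_equal(nrow(est$per_pore), 2)
  expect_equal(est$Delta_V, 0)
  expect_equal(est$m_V, est$per_pore$volume_pix3[1])
  expect_equal(sum(est$per_pore$volume_pix3), est$V_sigma)
})

test_that("estimated volume scales as the cube of linear size", {
  v <- vapply(c(8, 16, 32), function(r) {
    est <- estimate_volumes(make_disk_region(r), delta = 1, method = "mean",
                            frame_area = (2 * r + 11)^2, scale = 1)
    est$V_sigma
  }, numeric(1))
  expect_equal(v[2] / v[1], 8, tolerance = 0.08)
  expect_equal(v[3] / v[2], 8, tolerance = 0.08)
})

test_that("sphere volume is recovered from its central section", {
  r <- 20
  est <- estimate_volumes(make_disk_region(r), delta = 1, method = "mean",
                          frame_area = (2 * r + 11)^2, scale = 1)
  truth <- 4 / 3 * pi * r^3
  expect_lt(abs(est$V_sigma - truth) / truth, 0.1)
})

test_that("border regions are excluded by default and scale converts units", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:5, 1:5] <- TRUE     # touches the border
  mask[10:15, 10:15] <- TRUE
  regs <- label_regions(mask, min_area = 1)
  est <- estimate_volumes(regs, delta = 1, frame_area = 400, scale = 0.5)
  expect_equal(nrow(est$per_pore), 1)
  expect_equal(est$per_pore$volume_um3, est$per_pore$volume_pix3 * 0.125)
  both <- estimate_volumes(regs, delta = 1, frame_area = 400, scale = 0.5,
                           include_border = TRUE)
  expect_equal(nrow(both$per_pore), 2)
  # nothing eligible: empty estimate with a warning
  only_border <- label_regions(matrix(TRUE, 4, 4), min_area = 1)
  expect_warning(
    empty <- estimate_volumes(only_border, frame_area = 16, scale = 1),
    "no eligible")
  expect_equal(empty$V_sigma, 0)
})

test_that("isotropy makes estimated g match the vertical-chord distribution", {
  # central sections of spheres: the estimated out-of-plane axes should be
  # located like the measured vertical chords themselves
  for (seed in c(1, 2, 3)) {
    sc <- generate_scene(6, dims = c(160, 160, 40), axis_meanlog = log(13),
                         axis_sdlog = 0.15, seed = seed)
    cs <- render_scene(sc, "cross-section")
    seg <- segment_pores(cs$image, epsilon = 10)
    g_est <- numeric(0)
    h_all <- numeric(0)
    for (reg in Filter(function(r) !r$touches_border, seg$regions$regions)) {
      ch <- horizontal_chords(reg, delta = 1)
      for (k in seq_len(nrow(ch$chords))) {
        row <- ch$chords[k, ]
        phi <- vertical_chords(reg, row$row, row$x_start, row$x_end)
        phi <- phi[phi > 0]
        if (length(phi)) {
          g_est <- c(g_est, estimate_g_mean(phi)$g)
          h_all <- c(h_all, phi)
        }
      }
    }
    p <- stats::t.test(g_est, h_all)$p.value
    expect_gt(p, 0.01)
  }
})
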