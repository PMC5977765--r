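test_that("scene generation is seeded, reproducible and validated", {
  sc <- generate_scene(1, dims = c(100, 100, 100), axis_meanlog = log(10),
                       axis_sdlog = 0, seed = 1)
  expect_equal(sc$true_volumes, 4 / 3 * pi * 10^3)
  expect_equal(sc$true_density, 4 / 3 * pi * 10^3 / 1e6)
  sc2 <- generate_scene(1, dims = c(100, 100, 100), axis_meanlog = log(10),
                        axis_sdlog = 0, seed = 1)
  expect_identical(sc, sc2)
  sc3 <- generate_scene(3, dims = c(100, 100, 100), seed = 2)
  expect_false(identical(sc$pores, sc3$pores))
  empty <- generate_scene(0, seed = 1)
  expect_equal(empty$true_density, 0)
  # global RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_scene(2, seed = 5))
  expect_identical(before, .Random.seed)
})

test_that("infeasible non-overlapping packings fail with a clear error", {
  expect_error(
    generate_scene(80, dims = c(60, 60, 60), axis_meanlog = log(12),
                   axis_sdlog = 0, allow_overlap = FALSE, max_retries = 10,
                   seed = 1),
    "without overlap|cannot fit")
})

test_that("voxelized volume converges to the analytic volume", {
  sc <- generate_scene(2, dims = c(80, 80, 80), axis_meanlog = log(8),
                       axis_sdlog = 0.1, seed = 7)
  truth <- sum(sc$true_volumes)
  coarse <- voxelized_volume(sc, step = 1)
  fine <- voxelized_volume(sc, step = 0.5)
  expect_lt(abs(fine - truth) / truth, abs(coarse - truth) / truth + 0.01)
  expect_lt(abs(fine - truth) / truth, 0.02)
})

test_that("cross-sections are elliptic disks of the expected area", {
  sc <- generate_scene(1, dims = c(100, 100, 100), axis_meanlog = log(10),
                       axis_sdlog = 0, seed = 1)
  cz <- sc$pores[[1]]$center[3]
  cs <- render_scene(sc, "cross-section", z0 = cz)
  expect_lt(abs(sum(cs$mask) - pi * 100) / (pi * 100), 0.05)
  # pixels inside the section are dark, others at background
  expect_true(all(cs$image$pixels[cs$mask] < 245))
  expect_true(all(cs$image$pixels[!cs$mask] == 255))
  expect_error(render_scene(sc, "cross-section", z0 = 500), "outside the slab")
})

test_that("depth renders encode depth linearly with exact endpoints", {
  sc <- generate_scene(1, dims = c(100, 100, 60), axis_meanlog = log(15),
                       axis_sdlog = 0, seed = 9)
  rd <- render_scene(sc, "depth-render", d_true = 30)
  # over the pore's deepest point the chord is 2*15 = 30 = d_true: beta = 0
  expect_equal(min(rd$image$pixels), 0)
  expect_lt(abs(max(rd$depth) - 30), 0.2)  # nearest pixel center to the apex
  # background pixels carry no depth
  expect_true(all(rd$image$pixels[rd$depth == 0] == 255))
})

test_that("noise is seeded and reproducible, off by default", {
  sc <- generate_scene(2, dims = c(80, 80, 40), seed = 3)
  a <- render_scene(sc, "cross-section", noise_sd = 5)
  b <- render_scene(sc, "cross-section", noise_sd = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  c <- render_scene(sc, "cross-section", noise_sd = 5, seed = 77)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("noise-free depth renders round-trip through the depth estimator", {
  sc <- generate_scene(4, dims = c(120, 120, 50), axis_meanlog = log(9),
                       axis_sdlog = 0.15, seed = 13)
  rd <- render_scene(sc, "depth-render")
  dm <- depth_map(rd$image, depth_model(10, d_max = 50))
  quant <- 50 / 245  # one brightness step of depth
  expect_lt(max(abs(dm$zeta - rd$depth)), quant)
})

test_that("chord estimator recovers sphere volumes from central sections", {
  sc <- generate_scene(1, dims = c(120, 120, 120), axis_meanlog = log(22),
                       axis_sdlog = 0, seed = 21)
  cz <- sc$pores[[1]]$center[3]
  cs <- render_scene(sc, "cross-section", z0 = cz)
  seg <- segment_pores(cs$image, epsilon = 10)
  est <- estimate_volumes(seg, delta = 1, method = "mean")
  truth <- sc$true_volumes[1]
  expect_lt(abs(est$V_sigma - truth) / truth, 0.1)
})

test_that("scene ground-truth table matches the pore parameters", {
  sc <- generate_scene(3, dims = c(100, 100, 60), seed = 11)
  tab <- scene_truth(sc)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$volume_pix3, sc$true_volumes)
  expect_equal(tab$a[2], sc$pores[[2]]$axes[1])
})
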