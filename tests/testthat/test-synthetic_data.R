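test_that("dispersal model validation and frozen walkers", {
  expect_error(dispersal_model(c(10, -5), c(1, 1)))
  expect_error(dispersal_model(10, -1))
  m0 <- dispersal_model(60, 0, n_individuals = 20)
  pos <- simulate_linear_dispersal(m0, 500, n_frames = 60, seed = 1)
  expect_true(all(pos == 0))
})

test_that("single-phase MSD grows like 2 D t", {
  D <- 8
  m <- dispersal_model(360, D, n_individuals = 200)
  pos <- simulate_linear_dispersal(m, 1e6, 360, seed = 42)
  msd <- colMeans(pos^2)
  slope <- unname(coef(lm(msd ~ attr(pos, "t")))[2])
  expect_equal(slope, 2 * D, tolerance = 0.15)
})

test_that("reflecting boundaries conserve individuals inside the tunnel", {
  m <- dispersal_model(200, 50, n_individuals = 100)
  pos <- simulate_linear_dispersal(m, 100, 200, seed = 3)
  expect_true(all(abs(pos) <= 100))
  expect_identical(dim(pos), c(100L, 200L))
  # folding is an involution-consistent reflection
  s <- c(-260, -140, -60, 0, 60, 140, 260)
  r <- spiralmaze:::reflect_positions(s, 100)
  expect_true(all(abs(r) <= 100))
  expect_equal(r[4], 0)
  expect_equal(r[5], 60)
  expect_equal(r[6], 60)   # 140 reflects at +100 to 60
})

test_that("two-phase simulation recovers its breakpoint by hinge fit", {
  m <- dispersal_model(c(120, 240), c(0.5, 5), n_individuals = 200)
  det <- simulated_positions(m, seed = 7)
  w <- window_average(msd_series(det, n_frames = 360)$msd, 15)
  fit <- fit_piecewise(w$t_mid, w$value, 1)
  expect_lt(abs(fit$psi - 120), 15)
  expect_gt(fit$slopes[2], fit$slopes[1])
})

test_that("rendering is reproducible and empty arenas show pure background", {
  geom <- fx_demo_maze()
  m <- dispersal_model(10, 5, n_individuals = 5)
  pos <- simulate_linear_dispersal(m, geom$arc_length / 2, 10, seed = 5)
  s1 <- render_sequence(geom, pos, resolution = 2, insect_length = 2,
                        seed = 11)
  s2 <- render_sequence(geom, pos, resolution = 2, insect_length = 2,
                        seed = 11)
  expect_identical(s1$frame(3), s2$frame(3))
  expect_identical(s1$ground_truth, s2$ground_truth)
  # no individuals: every frame is background plus noise; per-pixel median
  # over frames recovers the background within the noise scale
  empty <- render_sequence(geom, matrix(numeric(0), 0, 8), resolution = 2,
                           insect_length = 2, noise_sd = 2, seed = 12)
  med <- estimate_background(lapply(1:8, empty$frame))
  expect_lt(max(abs(med - empty$background)), 6)
})

test_that("rendered insects have the nominal pixel size", {
  # a 0.5 mm insect imaged at 16 px/mm spans ~8 px
  st <- straight_geometry(60, 10)
  pos <- matrix(c(-10, 0, 10), 3, 1)
  sq <- render_sequence(st, pos, resolution = 16, insect_length = 0.5,
                        noise_sd = 0, hidden_fraction = 0, seed = 2)
  det <- detect_frame(sq$frame(1), sq$background, 50)
  expect_identical(nrow(det), 3L)
  # nominal painted axes are 8 x 3.2 px; the thresholded extent of the
  # soft-edged body measures slightly larger
  expect_equal(2 * sq$insect_axes_px[1], 8)
  major <- sqrt(det$area * det$aspect_ratio * 4 / pi)
  expect_true(all(major > 6.5 & major < 10.5))
  expect_true(all(det$aspect_ratio > 1.6 & det$aspect_ratio < 3.6))
  expect_error(render_sequence(st, pos, resolution = 1, insect_length = 0.5),
               "fewer than 2 px")
})

test_that("ground truth positions lie inside the tunnel when visible", {
  geom <- fx_demo_maze()
  m <- dispersal_model(30, 20, n_individuals = 40)
  pos <- simulate_linear_dispersal(m, geom$arc_length / 2, 30, seed = 9)
  sq <- render_sequence(geom, pos, resolution = 2.5, insect_length = 2,
                        seed = 9)
  gt <- sq$ground_truth[sq$ground_truth$visible, ]
  mask <- sq$mask
  inside <- mask[cbind(pmin(pmax(floor(gt$y_px) + 1, 1), nrow(mask)),
                       pmin(pmax(floor(gt$x_px) + 1, 1), ncol(mask)))]
  expect_gt(mean(inside), 0.99)
  expect_true(all(abs(gt$s_mm) <= geom$arc_length / 2))
})

test_that("single-phase dispersal is accepted as diffusive by the LRT", {
  accept <- vapply(1:50, function(k) {
    m <- dispersal_model(360, 10, n_individuals = 200)
    det <- simulated_positions(m, half_length = 623, seed = 600 + k)
    cls <- classify_msd(robust_msd_series(det, 200))
    cls$p_values["p_0_vs_1"] >= 0.05
  }, TRUE)
  expect_gte(mean(accept), 0.9)
})
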