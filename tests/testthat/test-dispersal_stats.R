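test_that("MSD series basics", {
  det <- data.frame(frame = c(1, 1, 2, 2, 4), s_mm = c(0, 0, 3, -3, 5))
  ms <- msd_series(det, n_frames = 4)
  expect_equal(ms$msd, c(0, 9, NA, 25))
  expect_equal(ms$n, c(2L, 2L, 0L, 1L))
  ms2 <- msd_series(det, origin = 1, n_frames = 2)
  expect_equal(ms2$msd, c(1, (2^2 + 4^2) / 2))
})

test_that("window averaging reduces 360 points to 24", {
  w <- window_average(seq_len(360), 15)
  expect_identical(nrow(w), 24L)
  expect_equal(w$t_mid, (1:24 - 0.5) * 15)
  expect_equal(w$value[1], mean(1:15))
  expect_identical(nrow(window_average(1:7, 1)), 7L)
  expect_error(window_average(1:10, 20))
  # constant series: flat output, residual autocorrelation check passes
  wc <- window_average(rep(2, 60), 15)
  expect_true(all(wc$value == 2))
  expect_false(acf_lag1(wc$value - mean(wc$value))$significant)
})

test_that("robust MSD matches the plain MSD on uncensored Gaussian spread", {
  m <- dispersal_model(120, 10, n_individuals = 200)
  det <- simulated_positions(m, seed = 13, n_frames = 120)
  plain <- msd_series(det, n_frames = 120)
  rob <- robust_msd_series(det, 200, n_frames = 120)
  late <- 60:120
  expect_equal(mean(rob$msd[late] / plain$msd[late]), 1, tolerance = 0.1)
  # deleting the central half of the detections barely moves the estimate
  censored <- det[abs(det$s_mm) > ave(abs(det$s_mm), det$frame,
                                      FUN = function(z) quantile(z, 0.5)), ]
  rob_c <- robust_msd_series(censored, 200, n_frames = 120)
  expect_equal(mean(rob_c$msd[late] / rob$msd[late]), 1, tolerance = 0.05)
})

test_that("piecewise fits recover exact models", {
  t <- (1:24 - 0.5) * 15
  f0 <- fit_piecewise(t, 2 * t + 1, 0)
  expect_equal(unname(f0$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(f0$rss, 1e-16)
  th <- 1:24
  yh <- th + 2 * pmax(th - 10, 0)
  f1 <- fit_piecewise(th, yh, 1)
  expect_equal(f1$psi, 10, tolerance = 0.26)
  expect_lt(f1$rss, 1e-6)
  expect_equal(f1$slopes, c(1, 3), tolerance = 1e-3)
})

test_that("RSS never increases with added breakpoints", {
  set.seed(20)
  for (k in 1:5) {
    t <- (1:24 - 0.5) * 15
    y <- 0.5 * t + rnorm(24, 0, 20)
    fits <- lapply(0:2, function(nb) fit_piecewise(t, y, nb))
    rss <- vapply(fits, function(f) f$rss, 0)
    expect_true(all(diff(rss) <= 1e-9))
    a <- anova_piecewise(fits[[1]], fits[[2]])
    expect_true(a$p >= 0 && a$p <= 1)
  }
})

test_that("dispersal-type labels follow the slope rules", {
  t <- 1:24
  mk <- function(y) lapply(0:2, function(nb) fit_piecewise(t, y, nb))
  set.seed(30)
  eps <- rnorm(24, 0, 0.02)
  slow_fast <- cumsum(c(rep(0.2, 10), rep(2, 14))) + eps
  expect_identical(classify_dispersal(mk(slow_fast))$label, "type2")
  slow_fast_slow <- cumsum(c(rep(0.2, 8), rep(2.5, 8), rep(0.3, 8))) + eps
  expect_identical(classify_dispersal(mk(slow_fast_slow))$label, "type3")
  fast_slow_fast <- cumsum(c(rep(2.5, 8), rep(0.2, 8), rep(2.5, 8))) + eps
  expect_identical(classify_dispersal(mk(fast_slow_fast))$label, "other")
})

test_that("the levels LRT keeps noisy lines diffusive", {
  set.seed(42)
  lab <- replicate(50, {
    t <- (1:24 - 0.5) * 15
    y <- 2 * t + rnorm(24, 0, 30)
    classify_dispersal(lapply(0:2, function(k) fit_piecewise(t, y, k)))$label
  })
  expect_gte(mean(lab == "type1"), 0.9)
})

test_that("grid search matches an iterative-linearization oracle", {
  set.seed(50)
  for (k in 1:6) {
    t <- 1:24
    y <- cumsum(c(rep(0.5, 8), rep(2, 8), rep(0.8, 8))) + rnorm(24, 0, 1)
    f2 <- fit_piecewise(t, y, 2)
    oracle <- segmented_iterative_oracle(t, y, 2, n_restarts = 200,
                                         seed = k)
    expect_lte(f2$rss, oracle * 1.01)
  }
})

test_that("detection rate uses exact binomial intervals", {
  r <- detection_rate_ci(1817, 2535)
  expect_equal(round(100 * r$rate), 72)
  expect_false(r$flagged)
  cases <- list(c(1817, 2535), c(0, 50), c(50, 50), c(3, 10))
  for (cs in cases) {
    got <- detection_rate_ci(cs[1], cs[2])
    want <- clopper_pearson_oracle(cs[1], cs[2])
    expect_equal(got$lower, want[1], tolerance = 1e-6)
    expect_equal(got$upper, want[2], tolerance = 1e-6)
  }
  expect_equal(detection_rate_ci(0, 20)$lower, 0)
  expect_true(detection_rate_ci(30, 20)$flagged)
  expect_error(detection_rate_ci(5, 0))
})

test_that("chi-square homogeneity matches the textbook statistic", {
  a <- c(30, 25, 18, 11, 7, 4, 3, 1, 1, 0)
  b <- c(28, 27, 20, 10, 8, 5, 2, 2, 0, 1)
  got <- chi2_homogeneity(a, b)
  expect_identical(got$df, 9L)     # ten occupied bins
  expect_equal(got$statistic, chi2_oracle(a, b), tolerance = 1e-9)
  same <- chi2_homogeneity(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  set.seed(60)
  for (k in 1:5) {
    x <- rpois(5, 20)
    y <- rpois(5, 20)
    expect_equal(chi2_homogeneity(x, y)$statistic, chi2_oracle(x, y),
                 tolerance = 1e-9)
  }
  expect_error(chi2_homogeneity(c(0, 0), c(0, 0)))
})

test_that("skewness symmetry test behaves", {
  expect_equal(skewness_symmetry_test(c(-3, -2, -1, 0, 0, 1, 2, 3),
                                      n_mc = 100)$skewness, 0)
  expect_error(skewness_symmetry_test(rep(1, 20)))
  set.seed(70)
  p_exp <- vapply(1:10, function(k)
    skewness_symmetry_test(rexp(200), n_mc = 2000, seed = k)$p, 0)
  expect_true(all(p_exp < 0.01))
})

test_that("per-minute screens adjust with Bonferroni", {
  d <- data.frame(t = rep(1:5, each = 8),
                  value = rep(c(1, 2, 3, 4), times = 10),
                  group = rep(rep(c("L", "R"), each = 4), 5))
  # both groups see identical values at each minute: F = 0, p = 1
  scr <- per_minute_screen(d, "anova")
  expect_true(all(scr$p_adj == 1))
  expect_true(all(scr$p_raw >= 0.999))
  # adjusted p = raw p times the number of minutes, capped at 1
  set.seed(80)
  d2 <- data.frame(t = rep(1:6, each = 10), value = rnorm(60),
                   group = rep(c("L", "R"), 30))
  scr2 <- per_minute_screen(d2, "anova")
  expect_equal(scr2$p_adj, pmin(scr2$p_raw * 6, 1))
  expect_true(all(scr2$p_adj >= scr2$p_raw))
})

test_that("variance partition attributes strain share of sums of squares", {
  strains <- rep(paste0("S", 1:6), each = 4)
  y <- rep(c(1, 2, 3, 4, 5, 6), each = 4)
  vp <- variance_partition(data.frame(msd_final = y, strain = strains))
  expect_equal(vp$ratio, 1)
  vp0 <- variance_partition(data.frame(msd_final = rep(2, 24),
                                       strain = strains))
  expect_equal(vp0$ratio, 0)
  # with nuisance factors fitted first, their SS leaves the strain share
  set.seed(90)
  d <- data.frame(strain = strains, day = rep(c("a", "b"), 12),
                  msd_final = rep(1:6, each = 4) + rnorm(24, 0, 0.1))
  vps <- variance_partition(d, others = "day")
  expect_gt(vps$ratio, 0.9)
  expect_named(vps$ss, c("strain", "other", "residual"))
})

test_that("variance partition recovers a calibrated strain share", {
  # 8 strains x 10 replicates; strain and residual variances chosen so the
  # expected sequential-SS share of the strain term is one third
  set.seed(42)
  ratios <- replicate(100, {
    strains <- rep(paste0("S", 1:8), each = 10)
    mu <- rnorm(8, 0, sqrt(0.4066))
    y <- mu[rep(1:8, each = 10)] + rnorm(80, 0, 1)
    variance_partition(data.frame(msd_final = y, strain = strains))$ratio
  })
  expect_equal(mean(ratios), 0.33, tolerance = 0.05 / 0.33)
})
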