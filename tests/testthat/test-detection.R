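test_that("background estimation matches a sorting oracle", {
  set.seed(1)
  frames <- lapply(1:7, function(k) matrix(runif(30 * 20, 0, 255), 30, 20))
  expect_equal(estimate_background(frames), median_stack_oracle(frames))
  frames6 <- frames[1:6]   # even stack size
  expect_equal(estimate_background(frames6), median_stack_oracle(frames6))
  expect_equal(estimate_background(frames, "mean"),
               Reduce(`+`, frames) / 7)
  expect_error(estimate_background(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "identical dimensions")
})

test_that("the median background ignores transient particles", {
  bg <- matrix(200, 20, 20)
  frames <- lapply(1:9, function(k) {
    f <- bg
    f[k + 2, k + 2] <- 40   # dark blob visits each pixel once
    f
  })
  expect_equal(estimate_background(frames), bg)
  # a static scene is returned exactly
  expect_equal(estimate_background(list(bg, bg, bg)), bg)
})

test_that("frame detection measures dark particles on bright floor", {
  bg <- matrix(200, 40, 60)
  img <- bg
  for (i in 1:40) for (j in 1:60)
    if ((i - 20.2)^2 + (j - 30.4)^2 <= 16) img[i, j] <- 80
  d <- detect_frame(img, bg, 60)
  expect_identical(nrow(d), 1L)
  expect_equal(d$area, pi * 16, tolerance = 0.15)
  expect_gte(d$circularity, 0.85)
  expect_gte(d$solidity, 0.95)
  expect_equal(d$x, 29.9, tolerance = 0.02)
  expect_equal(d$y, 19.7, tolerance = 0.02)
  # identical frame and background: nothing to detect
  expect_identical(nrow(detect_frame(bg, bg, 60)), 0L)
  # global additive illumination change cancels in the difference
  expect_equal(detect_frame(img + 20, bg + 20, 60), d)
})

test_that("descriptor bounds hold for arbitrary blobs", {
  set.seed(4)
  bg <- matrix(200, 80, 80)
  img <- bg
  for (k in 1:12) {
    i <- sample(5:75, 1)
    j <- sample(5:75, 1)
    img[i:(i + sample(1:6, 1)), j:(j + sample(1:6, 1))] <- 50
  }
  d <- detect_frame(img, bg, 60, area_range = c(1, 1e5))
  expect_gt(nrow(d), 0)
  expect_true(all(d$circularity >= 0 & d$circularity <= 1))
  expect_true(all(d$solidity >= 0 & d$solidity <= 1))
  expect_true(all(d$aspect_ratio >= 1))
})

test_that("blob statistics agree with the EBImage reference", {
  set.seed(8)
  img <- matrix(0, 60, 60)
  centers <- cbind(c(15, 40, 30), c(15, 20, 45))
  for (k in 1:3)
    for (i in 1:60) for (j in 1:60)
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= (k + 2)^2)
        img[i, j] <- 1
  lab <- cpp_label8(img > 0)
  st <- cpp_blob_stats(lab)
  ref <- EBImage::computeFeatures.shape(EBImage::bwlabel(img))
  expect_identical(nrow(st), nrow(ref))
  expect_equal(sort(st[, "area"]), sort(unname(ref[, "s.area"])))
  refm <- EBImage::computeFeatures.moment(EBImage::bwlabel(img))
  # centroids agree (EBImage indexes pixel centres from 1, this package
  # from 0.5)
  expect_equal(sort(st[, "cy"]) + 0.5, sort(unname(refm[, "m.cx"])),
               tolerance = 1e-6)
})

test_that("pack-wise sequence analysis is deterministic and consistent", {
  geom <- fx_demo_maze()
  pos <- uniform_walkers(25, geom$arc_length / 2, 40, D = 25, seed = 21)
  sq <- render_sequence(geom, pos, resolution = 2, insect_length = 2,
                        noise_sd = 2, hidden_fraction = 0, seed = 22)
  det_packed <- analyze_sequence(sq, pack_size = 20, threshold = 50,
                                 area_range = c(3, 80))
  expect_true(all(diff(det_packed$frame) >= 0))
  # degenerate pack covering the whole sequence equals a single background
  frames <- lapply(seq_len(40), sq$frame)
  det_one <- analyze_sequence(frames, pack_size = 40, threshold = 50,
                              area_range = c(3, 80))
  bg <- estimate_background(frames)
  manual <- do.call(rbind, lapply(seq_len(40), function(k) {
    d <- detect_frame(frames[[k]], bg, 50, c(3, 80))
    if (nrow(d)) d$frame <- k
    d
  }))
  rownames(manual) <- NULL
  expect_equal(det_one, manual)
  # per-frame counts track the visible ground truth on a sparse clean scene
  gt_n <- table(factor(sq$ground_truth$frame[sq$ground_truth$visible],
                       levels = 1:40))
  det_n <- table(factor(det_packed$frame, levels = 1:40))
  expect_lt(mean(abs(as.integer(det_n) / as.integer(gt_n) - 1)), 0.05)
})

test_that("sequence analysis reads TIFF frames from disk", {
  geom <- fx_demo_maze()
  m <- dispersal_model(6, 25, n_individuals = 10)
  pos <- simulate_linear_dispersal(m, geom$arc_length / 2, 6, seed = 31)
  dir <- file.path(tempdir(), "frames_test")
  sq <- render_sequence(geom, pos, resolution = 2, insect_length = 2,
                        seed = 32, dir = dir)
  paths <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  expect_length(paths, 6)
  f3 <- read_frame_tiff(paths[3])
  expect_equal(f3, sq$frame(3), tolerance = 1e-8)
  det_disk <- analyze_sequence(paths, pack_size = 6, threshold = 50,
                               area_range = c(3, 80))
  det_mem <- analyze_sequence(sq, pack_size = 6, threshold = 50,
                              area_range = c(3, 80))
  expect_equal(det_disk, det_mem)
  unlink(dir, recursive = TRUE)
})

test_that("light profile is flat on uniform fields and calibrated linearly", {
  sk <- fx_demo_skeleton(2.5)
  img <- matrix(100, nrow(fx_demo_mask(2.5)), ncol(fx_demo_mask(2.5)))
  lp <- light_profile_along_path(img, sk, c(gain = 2, offset = 0))
  expect_equal(lp$mean_lux, 200)
  expect_equal(lp$max_rel_dev, 0)
  # a long-range horizontal gradient folds into waves with no |s| trend
  grad <- make_illumination_field(nrow(img), ncol(img), gradient = 0.14,
                                  vignette = 0)
  lp2 <- light_profile_along_path(img * grad, sk)
  expect_gt(lp2$max_rel_dev, 0.02)
  expect_lt(abs(lp2$spearman_abs_s), 0.2)
})
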