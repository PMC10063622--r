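make_detections <- function(n_frames = 100) {
  set.seed(11)
  # genuine insects: moving, plausible shape, inside the corridor
  insects <- data.frame(
    frame = rep(1:n_frames, each = 4),
    x = runif(4 * n_frames, 0, 400), y = runif(4 * n_frames, 0, 300),
    area = runif(4 * n_frames, 8, 30),
    circularity = runif(4 * n_frames, 0.6, 1),
    solidity = runif(4 * n_frames, 0.9, 1),
    aspect_ratio = runif(4 * n_frames, 1.5, 3),
    s_mm = runif(4 * n_frames, -600, 600),
    perp_mm = runif(4 * n_frames, 0, 3),
    truth = "insect"
  )
  # a dust speck: identical rounded position in every frame
  dust <- data.frame(frame = 1:n_frames, x = 123.2 + runif(n_frames, -0.1, 0.1),
                     y = 57.3 + runif(n_frames, -0.1, 0.1), area = 15,
                     circularity = 0.9, solidity = 1, aspect_ratio = 1.1,
                     s_mm = 210, perp_mm = 1, truth = "dust")
  # wall shadows: right at the corridor edge
  shadow <- data.frame(frame = sample(1:n_frames, 30), x = runif(30, 0, 400),
                       y = runif(30, 0, 300), area = 20, circularity = 0.8,
                       solidity = 1, aspect_ratio = 2,
                       s_mm = runif(30, -600, 600), perp_mm = 4.9,
                       truth = "shadow")
  # elongated streaks
  streak <- data.frame(frame = sample(1:n_frames, 25), x = runif(25, 0, 400),
                       y = runif(25, 0, 300), area = 40, circularity = 0.1,
                       solidity = 0.5, aspect_ratio = 8,
                       s_mm = runif(25, -600, 600), perp_mm = 2,
                       truth = "streak")
  # sub-pixel noise specks
  tiny <- data.frame(frame = sample(1:n_frames, 20), x = runif(20, 0, 400),
                     y = runif(20, 0, 300), area = 1, circularity = 1,
                     solidity = 1, aspect_ratio = 1,
                     s_mm = runif(20, -600, 600), perp_mm = 1,
                     truth = "tiny")
  rbind(insects, dust, shadow, streak, tiny)
}

test_that("the four filters remove their artifact classes", {
  det <- make_detections()
  cfg <- filter_config(area_min = 4, area_max = 80, circ_min = 0.4,
                       edge_max_frac = 0.9)
  res <- apply_filters(det, cfg, n_frames = 100, path_width = 10)
  kept <- res$detections
  expect_true(all(kept$truth == "insect"))
  expect_gte(nrow(kept) / sum(det$truth == "insect"), 0.95)
  expect_identical(unname(res$removed["redundancy"]), 100L)
  expect_identical(unname(res$removed["area"]), 20L)
  expect_identical(unname(res$removed["edge"]), 30L)
  expect_identical(unname(res$removed["circularity"]), 25L)
})

test_that("a particle seen in few frames is not redundant", {
  det <- data.frame(frame = c(1, 2), x = c(10, 10), y = c(10, 10),
                    area = 15, circularity = 0.9, solidity = 1,
                    aspect_ratio = 1.2, s_mm = 5, perp_mm = 1)
  res <- apply_filters(det, filter_config(area_min = 4, area_max = 80),
                       n_frames = 100, path_width = 10)
  expect_identical(res$n_kept, 2L)
})

test_that("filters are pure predicates: order-free membership, idempotent", {
  det <- make_detections()
  cfg <- filter_config(area_min = 4, area_max = 80, circ_min = 0.4)
  res1 <- apply_filters(det, cfg, n_frames = 100, path_width = 10)
  # membership from independently evaluated predicates
  key <- paste(round(det$x / cfg$redundancy_tol),
               round(det$y / cfg$redundancy_tol))
  frames_at <- tapply(det$frame, key, function(f) length(unique(f)))
  p_red <- !(key %in% names(frames_at)[frames_at > 0.5 * 100])
  p_area <- det$area >= 4 & det$area <= 80
  p_edge <- det$perp_mm <= 0.9 * 5
  p_circ <- det$circularity >= 0.4
  keep <- p_red & p_area & p_edge & p_circ
  expect_identical(res1$n_kept, sum(keep))
  # second application changes nothing (kept set has no redundant keys)
  res2 <- apply_filters(res1$detections, cfg, n_frames = 100,
                        path_width = 10)
  expect_identical(res2$n_kept, res1$n_kept)
  expect_identical(sum(res2$removed), 0L)
})

test_that("configuration bounds are validated", {
  expect_error(filter_config(redundancy_frac = 0))
  expect_error(filter_config(area_min = -1))
  expect_error(filter_config(edge_max_frac = 1.5))
})
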