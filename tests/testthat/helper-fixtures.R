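# shared fixtures (computed lazily, once per test run) and independent
# oracles used across the suite

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_demo_maze <- function() fixture("demo_maze", demo_maze())

fx_demo_mask <- function(res = 2.5) {
  fixture(paste0("demo_mask_", res), render_tunnel_mask(fx_demo_maze(), res))
}

fx_demo_skeleton <- function(res = 2.5) {
  fixture(paste0("demo_skel_", res), path_skeleton(fx_demo_mask(res)))
}

# a straight test corridor wrapped in a maze_geometry shell
straight_geometry <- function(length_mm = 100, width_mm = 10,
                              plate = c(length_mm + 20, width_mm + 20)) {
  x <- seq(-length_mm / 2, length_mm / 2, by = 0.5)
  structure(list(plate_width = plate[1], plate_height = plate[2],
                 path_width = width_mm, wall_width = 2, wall_height = 5,
                 centerline = cbind(x, 0), s = x,
                 arc_length = length_mm, wall_polygons = list()),
            class = "maze_geometry")
}

# ---- oracles ---------------------------------------------------------------

# per-pixel median by explicit sort (independent of the C++ kernel)
median_stack_oracle <- function(frames) {
  arr <- simplify2array(frames)
  apply(arr, c(1, 2), median)
}

# pixel-level ray casting for the occlusion model: a floor pixel is hidden
# iff a wall lies on the radial segment it shares with the camera ray
raycast_occlusion_oracle <- function(mask, wall_height, camera_height,
                                     n_steps = 9) {
  idx <- which(mask, arr.ind = TRUE)
  px <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
  ax <- c(ncol(mask) / 2, nrow(mask) / 2)
  hidden <- rep(FALSE, nrow(px))
  for (tt in seq(1 - wall_height / camera_height, 1 - 1e-6,
                 length.out = n_steps)) {
    q1 <- ax[1] + tt * (px[, 1] - ax[1])
    q2 <- ax[2] + tt * (px[, 2] - ax[2])
    r <- pmin(pmax(floor(q2) + 1, 1), nrow(mask))
    cc <- pmin(pmax(floor(q1) + 1, 1), ncol(mask))
    hidden <- hidden | !mask[cbind(r, cc)]
  }
  mean(hidden)
}

# Clopper-Pearson interval by bisection on binomial tail probabilities
clopper_pearson_oracle <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

# textbook chi-square homogeneity statistic
chi2_oracle <- function(a, b) {
  keep <- a + b > 0
  tab <- rbind(a[keep], b[keep])
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Muggeo-style iterative-linearization fit of a 1- or 2-breakpoint hinge
# model, with random restarts; returns the best RSS found
segmented_iterative_oracle <- function(t, y, n_bp, n_restarts = 200,
                                       seed = 1) {
  best <- Inf
  rng <- range(t)
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      psi <- sort(runif(n_bp, rng[1], rng[2]))
      for (it in 1:30) {
        U <- sapply(psi, function(p) pmax(t - p, 0))
        V <- sapply(psi, function(p) -(t > p))
        X <- cbind(1, t, U, V)
        f <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
        if (is.null(f)) break
        beta <- f$coefficients
        d <- beta[3:(2 + n_bp)]
        g <- beta[(3 + n_bp):(2 + 2 * n_bp)]
        step <- g / d
        step[!is.finite(step)] <- 0
        psi_new <- psi + step
        psi_new <- pmin(pmax(psi_new, rng[1] + 1e-6), rng[2] - 1e-6)
        if (max(abs(psi_new - psi)) < 1e-6) {
          psi <- psi_new
          break
        }
        psi <- sort(psi_new)
      }
      U <- sapply(psi, function(p) pmax(t - p, 0))
      f <- .lm.fit(cbind(1, t, U), y)
      rss <- sum(f$residuals^2)
      if (is.finite(rss) && rss < best) best <- rss
    }
  })
  best
}

# random walkers starting uniformly spread along the tunnel (a resolvable
# "clean" scene, free of the release-clump overlaps)
uniform_walkers <- function(n, half_length, n_frames, D, seed) {
  set.seed(seed)
  s <- runif(n, -0.9 * half_length, 0.9 * half_length)
  out <- matrix(NA_real_, n, n_frames)
  for (k in seq_len(n_frames)) {
    s <- s + rnorm(n, 0, sqrt(2 * D))
    s <- spiralmaze:::reflect_positions(s, half_length)
    out[, k] <- s
  }
  out
}

# simulate an unrendered assay: per-frame arc positions as a detection table
simulated_positions <- function(model, half_length = 1e6, n_frames = 360,
                                seed = 1) {
  pos <- simulate_linear_dispersal(model, half_length, n_frames, 1,
                                   seed = seed)
  data.frame(frame = rep(seq_len(n_frames), each = nrow(pos)),
             s_mm = as.vector(pos))
}
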