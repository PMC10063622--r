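#' Mean squared displacement series
#'
#' MSD at time `t` is the mean over the detections of that frame of the
#' squared signed arc distance from the introduction point. Detections (not
#' tracked individuals) are the sampling unit: no identity linking is
#' performed. For a group released at `s = 0`, the MSD equals the variance
#' of the spatial distribution and grows as `2 D t` under simple diffusion.
#'
#' @param positions data frame with columns `frame` and `s_mm`.
#' @param dt minutes per frame.
#' @param origin reference point (mm) on the arc coordinate.
#' @param n_frames total frame count; frames without any detection yield
#'   `NA` (not zero).
#' @return data frame: `t` (min), `msd` (mm^2), `n` (detections).
#' @export
msd_series <- function(positions, dt = 1, origin = 0, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(positions$frame)
  sq <- (positions$s_mm - origin)^2
  msd <- tapply(sq, factor(positions$frame, levels = seq_len(n_frames)), mean)
  n <- tapply(sq, factor(positions$frame, levels = seq_len(n_frames)), length)
  data.frame(t = seq_len(n_frames) * dt, msd = as.numeric(msd),
             n = ifelse(is.na(n), 0L, as.integer(n)))
}

#' Censoring-robust MSD series from upper order statistics
#'
#' When a compact group is released at one point, individuals overlap near the
#' release point and per-frame particle analysis undercounts the centre of the
#' distribution, inflating the plain MSD. The upper order statistics of |s|
#' are unaffected by that central censoring: the m-th largest |s| among the
#' detections equals the m-th largest among all individuals as long as the
#' sparse tails are detected. This estimator matches the mean of the ranked
#' tail (ranks `rank_range` of the released count, default the top 5-15 %)
#' to the corresponding folded-normal order-statistic means, yielding a
#' variance estimate that tracks the true MSD under diffusive (Gaussian)
#' spread even when most central detections are missing.
#'
#' Frames with fewer detections than the deepest rank fall back to the plain
#' mean of squares (flagged in the `fallback` column); with few detections
#' the group is either sparse (plain MSD unbiased) or still clumped at the
#' origin (MSD near zero).
#'
#' @param positions data frame with columns `frame` and `s_mm`.
#' @param n_released number of individuals released into the maze.
#' @param rank_range tail rank window as fractions of `n_released`.
#' @param multiplicity optional integer vector (one value per detection):
#'   estimated number of individuals per detected particle (e.g.
#'   `pmax(1, round(area / single_body_area))`). Two touching individuals
#'   merge into one particle; expanding detections by their multiplicity
#'   before ranking keeps the tail ranks aligned with the released count.
#' @param dt,origin,n_frames as in [msd_series()].
#' @return data frame: `t`, `msd`, `n`, `fallback`.
#' @export
robust_msd_series <- function(positions, n_released,
                              rank_range = c(0.05, 0.15),
                              multiplicity = NULL, dt = 1,
                              origin = 0, n_frames = NULL) {
  stopifnot(n_released >= 20)
  if (is.null(n_frames)) n_frames <- max(positions$frame)
  m1 <- max(2, round(rank_range[1] * n_released))
  m2 <- max(m1 + 2, round(rank_range[2] * n_released))
  abs_s <- abs(positions$s_mm - origin)
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(abs_s))
  fr <- factor(positions$frame, levels = seq_len(n_frames))
  by_frame <- split(abs_s, fr)
  by_mult <- split(as.integer(pmax(multiplicity, 1L)), fr)
  est <- vapply(seq_len(n_frames), function(k) {
    s <- rep(by_frame[[k]], by_mult[[k]])
    # adapt the rank depth to the frame's (multiplicity-corrected) count so
    # the estimator never reaches into the censored centre of the sample
    m2e <- min(m2, floor(0.8 * length(s)))
    if (m2e >= m1 + 2) {
      zbar <- mean(qnorm(1 - (m1:m2e) / (2 * n_released)))
      c((mean(sort(s, decreasing = TRUE)[m1:m2e]) / zbar)^2,
        length(by_frame[[k]]), 0)
    } else if (length(s) > 0) c(mean(s^2), length(by_frame[[k]]), 1)
    else c(NA_real_, 0, 1)
  }, numeric(3))
  out <- data.frame(t = seq_len(n_frames) * dt, msd = est[1, ],
                    n = as.integer(est[2, ]), fallback = est[3, ] > 0)
  # under H0 diffusion the boundary increments of this estimator have
  # variance growing as (2t+h)^1.2 (empirically calibrated exponent; plain
  # MSD increments have exponent 1); used by classify_msd's WLS weights
  attr(out, "variance_power") <- 1.2
  out
}

#' Average a per-minute series over non-overlapping time windows
#'
#' Consecutive blocks of `window` values are averaged (`NA` values are
#' dropped within a block); a trailing remainder shorter than `window` is
#' truncated. 360 per-minute values with the default 15-min window yield 24
#' averaged points.
#'
#' @param values per-minute numeric vector.
#' @param window window length in samples.
#' @param dt minutes per sample.
#' @return data frame: `t_mid` (window midpoint, min), `value`, `n_used`.
#' @export
window_average <- function(values, window = 15, dt = 1) {
  stopifnot(window >= 1, window <= length(values))
  n_win <- length(values) %/% window
  idx <- rep(seq_len(n_win), each = window)
  v <- values[seq_len(n_win * window)]
  data.frame(
    t_mid = (seq_len(n_win) - 0.5) * window * dt,
    value = as.numeric(tapply(v, idx, function(z) mean(z, na.rm = TRUE))),
    n_used = as.integer(tapply(v, idx, function(z) sum(!is.na(z))))
  )
}

#' Lag-1 autocorrelation check of regression residuals
#'
#' @param resid residual vector.
#' @return list: `acf1`, `bound` (`1.96/sqrt(n)`), `significant`.
#' @export
acf_lag1 <- function(resid) {
  resid <- resid[!is.na(resid)]
  n <- length(resid)
  if (n < 3 || stats::sd(resid) == 0)
    return(list(acf1 = 0, bound = if (n > 0) 1.96 / sqrt(n) else NA_real_,
                significant = FALSE))
  a <- acf(resid, lag.max = 1, plot = FALSE)$acf[2]
  list(acf1 = a, bound = 1.96 / sqrt(n), significant = abs(a) > 1.96 / sqrt(n))
}

#' Continuous piecewise-linear (segmented) regression
#'
#' Fits `y = b0 + b1 t + sum_k d_k (t - psi_k)_+` with 0, 1 or 2
#' breakpoints. Breakpoint locations are found by exhaustive search on a
#' fine grid between the observed times (every candidate leaves at least
#' `min_seg` points per segment); conditional on the breakpoints the model
#' is linear and solved by OLS, and the global minimum-RSS solution is
#' returned. Deterministic; ties resolved towards the earliest breakpoints.
#'
#' @param t,y data vectors (`NA` pairs dropped).
#' @param n_breakpoints 0, 1 or 2.
#' @param grid_res breakpoint grid resolution; default a quarter of the
#'   median time step.
#' @param min_seg minimal number of points per segment.
#' @param max_candidates cap on grid size (the grid is coarsened above it).
#' @return an object of class `piecewise_fit`: list with `n_breakpoints`,
#'   `psi`, `coefficients`, `slopes` (one per segment), `rss`, `fitted`,
#'   `residuals`, `n`, `df_residual`, `acf_segments` (lag-1 residual
#'   autocorrelation per segment, via [acf_lag1()]).
#' @export
fit_piecewise <- function(t, y, n_breakpoints = 0, grid_res = NULL,
                          min_seg = 2, max_candidates = 200) {
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]
  y <- y[ok]
  o <- order(t)
  t <- t[o]
  y <- y[o]
  n <- length(t)
  stopifnot(n_breakpoints %in% 0:2)
  if (n < 2 * (1 + n_breakpoints))
    stop("too few points for the requested segmentation")
  hinge_fit <- function(psi) {
    X <- cbind(1, t)
    for (p in psi) X <- cbind(X, pmax(t - p, 0))
    f <- .lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients,
         fitted = y - f$residuals, residuals = f$residuals)
  }
  psi <- numeric(0)
  if (n_breakpoints > 0) {
    if (is.null(grid_res)) grid_res <- stats::median(diff(t)) / 4
    lo <- t[min_seg]
    hi <- t[n - min_seg + 1]
    if (hi <= lo) stop("too few points for the requested segmentation")
    cand <- seq(lo, hi, by = grid_res)
    if (length(cand) > max_candidates)
      cand <- seq(lo, hi, length.out = max_candidates)
    valid <- vapply(cand, function(p)
      sum(t < p) >= min_seg && sum(t > p) >= min_seg, TRUE)
    cand <- cand[valid]
    if (n_breakpoints == 1) {
      rs <- vapply(cand, function(p) hinge_fit(p)$rss, 0)
      psi <- cand[which.min(rs)]
    } else {
      gap <- min_seg * stats::median(diff(t))
      best <- Inf
      for (i in seq_along(cand)) {
        for (j in seq_along(cand)) {
          if (cand[j] < cand[i] + gap) next
          if (sum(t > cand[i] & t < cand[j]) < min_seg) next
          r <- hinge_fit(c(cand[i], cand[j]))$rss
          if (r < best - 1e-12) {
            best <- r
            psi <- c(cand[i], cand[j])
          }
        }
      }
      if (!length(psi)) stop("no feasible breakpoint pair")
    }
  }
  f <- hinge_fit(psi)
  slopes <- cumsum(f$coef[-1])
  seg_id <- findInterval(t, psi) + 1
  structure(list(
    n_breakpoints = n_breakpoints, psi = psi,
    coefficients = f$coef, slopes = as.numeric(slopes),
    rss = f$rss, fitted = f$fitted, residuals = f$residuals,
    t = t, y = y, n = n, df_residual = n - (2 + 2 * n_breakpoints),
    acf_segments = lapply(split(f$residuals, seg_id), acf_lag1)
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("piecewise fit: %d breakpoint(s)%s; slopes %s; RSS %.4g\n",
              x$n_breakpoints,
              if (length(x$psi)) paste0(" at ",
                                        paste(signif(x$psi, 4),
                                              collapse = ", ")) else "",
              paste(signif(x$slopes, 4), collapse = ", "), x$rss))
  invisible(x)
}

#' F-type likelihood-ratio test between nested piecewise fits
#'
#' Compares two [fit_piecewise()] objects on the same data; each additional
#' breakpoint accounts for 2 parameters (location and slope change).
#'
#' @param fit0,fit1 nested fits (`fit1` has more breakpoints).
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
anova_piecewise <- function(fit0, fit1) {
  stopifnot(fit1$n_breakpoints > fit0$n_breakpoints, fit0$n == fit1$n)
  df1 <- 2 * (fit1$n_breakpoints - fit0$n_breakpoints)
  df2 <- fit1$df_residual
  if (fit1$rss <= 0) {
    p <- if (fit0$rss <= 1e-12) 1 else 0
    return(list(F = Inf, df1 = df1, df2 = df2, p = p))
  }
  Fv <- ((fit0$rss - fit1$rss) / df1) / (fit1$rss / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# weighted piecewise-constant fits with 0, 1 and 2 jumps via prefix sums;
# the 2-jump stage rescales weights by the per-segment residual variance of
# the accepted 1-jump model (a slope change also changes increment variance)
jump_fit <- function(y, w0, stage2 = TRUE) {
  n <- length(y)
  if (n < 4) stop("too few window boundaries for phase classification")
  stage2 <- stage2 && n >= 7
  prefix <- function(w) {
    list(cw = c(0, cumsum(w)), cwy = c(0, cumsum(w * y)),
         cwy2 = c(0, cumsum(w * y^2)))
  }
  # rss of segment (i+1)..j with 0-padded prefixes (i, j are 0-based ends)
  seg_rss <- function(p, i, j) {
    sw <- p$cw[j + 1] - p$cw[i + 1]
    sy <- p$cwy[j + 1] - p$cwy[i + 1]
    pmax(p$cwy2[j + 1] - p$cwy2[i + 1] - sy^2 / sw, 0)
  }
  seg_mean <- function(p, i, j) {
    (p$cwy[j + 1] - p$cwy[i + 1]) / (p$cw[j + 1] - p$cw[i + 1])
  }
  p0 <- prefix(w0)
  rss0 <- seg_rss(p0, 0, n)
  splits <- 2:(n - 2)
  r1 <- seg_rss(p0, 0, splits) + seg_rss(p0, splits, n)
  i1 <- splits[which.min(r1)]
  best1 <- min(r1)
  F1 <- if (best1 > 0) ((rss0 - best1) / 2) / (best1 / (n - 3)) else
    if (rss0 > 0) Inf else NaN
  out <- list(mean0 = seg_mean(p0, 0, n), rss0 = rss0,
              i1 = i1, best1 = best1, F1 = F1,
              means1 = c(seg_mean(p0, 0, i1), seg_mean(p0, i1, n)))
  # per-segment variance of the w0-standardized values, from median squared
  # successive differences: robust to a further level shift inside the
  # segment (which would inflate an RSS-based estimate and mask it)
  vseg <- function(i, j) {
    z <- y[(i + 1):j] * sqrt(w0[(i + 1):j])
    if (length(z) >= 4) max(median(diff(z)^2) / 0.9098, 1e-300)
    else max(seg_rss(p0, i, j) / max(j - i - 1, 1), 1e-300)
  }
  out$v1 <- vseg(0, i1)
  out$v2 <- vseg(i1, n)
  if (!stage2) return(out)
  # stage-2 weights from the local increment variance (rolling median of
  # squared successive differences): under diffusion the variance of the
  # rate estimates follows the local MSD growth, so slow phases are far
  # more precise than a global t-scaling suggests; the median makes the
  # estimate robust to the level jumps being tested
  d2 <- diff(y)^2
  vloc <- vapply(seq_len(n), function(k) {
    lo <- max(1, k - 3)
    hi <- min(n - 1, k + 2)
    median(d2[lo:hi])
  }, 0) / (2 * 0.4549)
  vfloor <- 0.02 * median(d2) / (2 * 0.4549)
  out$vloc <- pmax(vloc, vfloor, 1e-300)
  w1 <- 1 / out$vloc
  p1 <- prefix(w1)
  rss1w <- seg_rss(p1, 0, i1) + seg_rss(p1, i1, n)
  is <- 2:(n - 4)
  js <- 4:(n - 2)
  head_r <- seg_rss(p1, 0, is)
  tail_r <- seg_rss(p1, js, n)
  M <- outer(is, js, function(i, j) ifelse(j >= i + 2,
                                           seg_rss(p1, i, j), Inf))
  tot <- head_r + M + rep(tail_r, each = length(is))
  k <- arrayInd(which.min(tot), dim(tot))
  j2 <- c(is[k[1]], js[k[2]])
  best2 <- min(tot)
  F12 <- if (best2 > 0) ((rss1w - best2) / 2) / (best2 / (n - 5)) else
    if (rss1w > 0) Inf else NaN
  out$w1 <- w1
  out$rss1w <- rss1w
  out$j2 <- j2
  out$best2 <- best2
  out$F12 <- F12
  out$means2 <- c(seg_mean(p1, 0, j2[1]), seg_mean(p1, j2[1], j2[2]),
                  seg_mean(p1, j2[2], n))
  out
}

# lag-1 moving-average coefficient of the boundary increments under H0:
# averaging the boundary values over +/- boundary_halfwidth minutes makes
# adjacent increments share noise (correlation ~0.14 at the defaults,
# calibrated once by simulation); the bootstrap nulls reproduce it
.boot_ma_theta <- 0.14

ma1_noise <- function(n, theta = .boot_ma_theta) {
  u <- rnorm(n + 1)
  (u[-1] + theta * u[-(n + 1)]) / sqrt(1 + theta^2)
}

# parametric-bootstrap p-values for the sup-F statistics of jump_fit,
# adjusting for the search over jump locations
jump_null_boot <- function(y, w0, fit, n_boot = 499) {
  n <- length(y)
  if (fit$rss0 <= 1e-12 * max(abs(y), 1)^2)
    return(list(p01 = 1, p12 = 1))
  if (is.null(fit$F12)) {
    F1s <- vapply(seq_len(n_boot), function(r)
      jump_fit(ma1_noise(n) / sqrt(w0), w0, stage2 = FALSE)$F1, 0)
    return(list(p01 = (1 + sum(F1s >= fit$F1)) / (n_boot + 1),
                p12 = NA_real_))
  }
  F1s <- F12s <- numeric(n_boot)
  sd0 <- 1 / sqrt(w0)
  m1j <- c(rep(fit$means1[1], fit$i1), rep(fit$means1[2], n - fit$i1))
  # conditional null for the second jump: 1-jump mean profile plus noise
  # with the data's own (jump-robust) local variance profile
  sd1 <- sqrt(fit$vloc)
  for (r in seq_len(n_boot)) {
    z <- ma1_noise(n)
    F1s[r] <- jump_fit(z * sd0, w0, stage2 = FALSE)$F1
    F12s[r] <- jump_fit(m1j + ma1_noise(n) * sd1, w0)$F12
  }
  list(p01 = (1 + sum(F1s >= fit$F1)) / (n_boot + 1),
       p12 = (1 + sum(F12s >= fit$F12)) / (n_boot + 1))
}

# label a slope sequence according to the dispersal-type rules
label_slopes <- function(k, slopes) {
  if (k == 0) return("type1")
  if (k == 1) return(if (slopes[2] > slopes[1]) "type2" else "other")
  if (slopes[1] < slopes[2] && slopes[3] < slopes[2]) "type3" else "other"
}

#' Classify dispersal dynamics from nested piecewise fits
#'
#' Forward model selection by F-type likelihood-ratio tests (0 vs 1 vs 2
#' breakpoints, alpha level per test); the most complex significantly better
#' model is retained and labelled by its slope pattern: no breakpoint =
#' `type1` (diffusive); one breakpoint with a faster second phase = `type2`
#' (latency then fast spread); two breakpoints with a slow-fast-slow pattern
#' = `type3`; anything else = `other`.
#'
#' This selection assumes approximately independent errors; for the MSD
#' series of a single assay (where errors are serially correlated because
#' the same individuals are measured throughout) use [classify_msd()].
#'
#' @param fits list of three [fit_piecewise()] objects with 0, 1 and 2
#'   breakpoints on identical data.
#' @param alpha significance level of each LRT.
#' @return an object of class `dispersal_type`: list with `label`,
#'   `n_breakpoints`, `breakpoints`, `slopes`, `p_values`.
#' @export
classify_dispersal <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) == 3)
  k <- vapply(fits, function(f) f$n_breakpoints, 0L)
  fits <- fits[order(k)]
  p01 <- anova_piecewise(fits[[1]], fits[[2]])$p
  sel <- 1L
  if (!is.na(p01) && p01 < alpha) {
    sel <- 2L
    p12 <- anova_piecewise(fits[[2]], fits[[3]])$p
    if (!is.na(p12) && p12 < alpha) sel <- 3L
  } else {
    p12 <- NA_real_
  }
  f <- fits[[sel]]
  structure(list(label = label_slopes(f$n_breakpoints, f$slopes),
                 n_breakpoints = f$n_breakpoints,
                 breakpoints = f$psi, slopes = f$slopes,
                 p_values = c(p_0_vs_1 = p01, p_1_vs_2 = p12),
                 method = "levels"),
            class = "dispersal_type")
}

#' @export
print.dispersal_type <- function(x, ...) {
  cat(sprintf("dispersal type: %s (%d breakpoint(s)%s; slopes %s)\n",
              x$label, x$n_breakpoints,
              if (length(x$breakpoints)) paste0(" at ",
                                                paste(signif(x$breakpoints, 4),
                                                      collapse = ", ")) else "",
              paste(signif(x$slopes, 3), collapse = ", ")))
  invisible(x)
}

#' Classify dispersal dynamics from a single-assay MSD series
#'
#' The MSD of one assay is measured on the same group of individuals at
#' every time point, so its sampling error is serially correlated and an
#' ordinary regression LRT on the MSD levels grossly overstates the
#' evidence for breakpoints. This classifier instead works on the MSD
#' *increments* between window boundaries, which are martingale differences
#' (uncorrelated between windows) under the random-walk model, and whose
#' variance grows as `2 t + h` under a constant diffusion coefficient; the
#' piecewise-constant growth rate is fitted by weighted least squares with
#' exhaustive search over jump locations, and the number of phases is
#' selected by F-type LRTs (2 parameters per added phase: location and
#' level).
#'
#' The boundary MSD value is averaged over `boundary_halfwidth` minutes on
#' each side of the boundary to damp detection-sampling noise.
#'
#' @param msd data frame from [msd_series()] or [robust_msd_series()]
#'   (per-minute `t`, `msd`).
#' @param window window length (min).
#' @param alpha LRT significance level.
#' @param boundary_halfwidth minutes averaged around each window boundary.
#' @param variance_power exponent `a` of the H0 increment-variance model
#'   `Var ~ (2t+h)^a`; defaults to the series' `variance_power` attribute
#'   (1.2 for the order-statistic estimator) or 1 (plain MSD).
#' @return a `dispersal_type` object; `slopes` are the per-phase MSD growth
#'   rates (mm^2/min, i.e. `2 D`), `breakpoints` the phase-change times
#'   (min, at window-boundary resolution).
#' @export
classify_msd <- function(msd, window = 15, alpha = 0.05,
                         boundary_halfwidth = 7, variance_power = NULL) {
  if (is.null(variance_power))
    variance_power <- attr(msd, "variance_power") %||% 1
  b <- seq(window, max(msd$t), by = window)
  bval <- vapply(b, function(tb) {
    v <- msd$msd[abs(msd$t - tb) <= boundary_halfwidth]
    mean(v, na.rm = TRUE)
  }, 0)
  if (anyNA(bval)) stop("MSD series has empty window boundaries")
  y <- diff(c(0, bval)) / window
  tl <- c(0, b[-length(b)])
  # H0 (constant-D) variance model of the increments: Var ~ (2t+h)^a
  w0 <- 1 / (2 * tl + window)^variance_power
  n <- length(y)
  fit <- jump_fit(y, w0)
  # p-values by parametric bootstrap of the sup-F statistics: exact
  # selection-adjusted calibration under the Gaussian working model
  boot <- with_seed(20240515L, jump_null_boot(y, w0, fit, n_boot = 499))
  p01 <- boot$p01
  if (is.na(p01) || p01 >= alpha) {
    res <- list(label = "type1", n_breakpoints = 0L, breakpoints = numeric(0),
                slopes = fit$mean0, p_values = c(p_0_vs_1 = p01,
                                                 p_1_vs_2 = NA))
  } else if (!is.na(boot$p12) && boot$p12 < alpha) {
    res <- list(label = label_slopes(2L, fit$means2), n_breakpoints = 2L,
                breakpoints = b[fit$j2], slopes = fit$means2,
                p_values = c(p_0_vs_1 = p01, p_1_vs_2 = boot$p12))
  } else {
    res <- list(label = label_slopes(1L, fit$means1), n_breakpoints = 1L,
                breakpoints = b[fit$i1], slopes = fit$means1,
                p_values = c(p_0_vs_1 = p01, p_1_vs_2 = boot$p12))
  }
  res$method <- "increments"
  structure(res, class = "dispersal_type")
}

#' Detection rate with exact binomial confidence interval
#'
#' @param auto_count automatically detected individuals.
#' @param manual_count manually scored individuals (ground truth).
#' @param confidence confidence level.
#' @return list: `rate`, `lower`, `upper` (Clopper-Pearson), `flagged`
#'   (`TRUE` when `auto_count > manual_count`, in which case the interval is
#'   `NA`).
#' @export
detection_rate_ci <- function(auto_count, manual_count, confidence = 0.95) {
  if (manual_count <= 0) stop("manual_count must be positive")
  rate <- auto_count / manual_count
  if (auto_count > manual_count)
    return(list(rate = rate, lower = NA_real_, upper = NA_real_,
                flagged = TRUE))
  ci <- stats::binom.test(auto_count, manual_count,
                          conf.level = confidence)$conf.int
  list(rate = rate, lower = ci[1], upper = ci[2], flagged = FALSE)
}

#' Chi-square homogeneity test between two binned distributions
#'
#' Tests whether two count distributions over the same spatial bins differ,
#' as a 2 x k contingency table (df = k - 1 after dropping bins empty in
#' both distributions).
#'
#' @param dist_a,dist_b integer count vectors over identical bins.
#' @return list: `statistic`, `df`, `p`.
#' @export
chi2_homogeneity <- function(dist_a, dist_b) {
  stopifnot(length(dist_a) == length(dist_b))
  keep <- dist_a + dist_b > 0
  if (!any(keep)) stop("all bins are empty")
  tab <- rbind(dist_a[keep], dist_b[keep])
  if (sum(keep) < 2)
    return(list(statistic = 0, df = 0L, p = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

# sample skewness b1 = m3 / m2^(3/2)
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

#' Monte-Carlo skewness test of distribution symmetry
#'
#' Compares the sample skewness to 0 by a two-sided Monte-Carlo test
#' against Gaussian samples of the same size.
#'
#' @param x sample (n >= 8).
#' @param n_mc Monte-Carlo replicates.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return list: `skewness`, `p`.
#' @export
skewness_symmetry_test <- function(x, n_mc = 1e4, seed = .default_seed) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 8)
  if (stats::sd(x) == 0) stop("zero-variance sample")
  b1 <- sample_skewness(x)
  null_b1 <- with_seed(seed, {
    M <- matrix(rnorm(n * n_mc), n, n_mc)
    m1 <- colMeans(M)
    M <- M - rep(m1, each = n)
    m2 <- colMeans(M^2)
    colMeans(M^3) / m2^1.5
  })
  p <- (1 + sum(abs(null_b1) >= abs(b1))) / (n_mc + 1)
  list(skewness = b1, p = p)
}

#' Per-minute statistical screen with Bonferroni correction
#'
#' Applies a test at every time point of a series and adjusts the p-values
#' for the number of time points (Bonferroni: multiplied by the number of
#' tests, capped at 1).
#'
#' * `test = "anova"`: one-way ANOVA of `value ~ group` at each time
#'   (e.g. MSD explained by maze rotation direction).
#' * `test = "skewness"`: [skewness_symmetry_test()] of `value` at each time
#'   (e.g. symmetry of the position distribution about the centre).
#'
#' @param data data frame with columns `t`, `value`, and (for anova)
#'   `group`.
#' @param test `"anova"` or `"skewness"`.
#' @param n_mc,seed Monte-Carlo settings for the skewness test.
#' @return data frame: `t`, `p_raw`, `p_adj`.
#' @export
per_minute_screen <- function(data, test = c("anova", "skewness"),
                              n_mc = 2000, seed = .default_seed) {
  test <- match.arg(test)
  ts <- sort(unique(data$t))
  p_raw <- vapply(seq_along(ts), function(k) {
    d <- data[data$t == ts[k], , drop = FALSE]
    if (test == "anova") {
      if (length(unique(d$group)) < 2) return(NA_real_)
      fit <- stats::lm(value ~ factor(group), data = d)
      a <- stats::anova(fit)
      a$`Pr(>F)`[1]
    } else {
      if (length(d$value) < 8 || stats::sd(d$value) == 0) return(NA_real_)
      skewness_symmetry_test(d$value, n_mc = n_mc, seed = seed + k)$p
    }
  }, 0)
  data.frame(t = ts, p_raw = p_raw,
             p_adj = pmin(p_raw * sum(!is.na(p_raw)), 1))
}

#' Partition of MSD variance attributable to strain
#'
#' Sequential (type-I) ANOVA of the final MSD per replicate on the nuisance
#' factors (replicate day, detection count, maze orientation) followed by
#' strain, returning the ratio `SST(strain) / (SSR + SST(strain) +
#' SST(other))`, i.e. the share of total variance attributed to the strain
#' effect.
#'
#' @param data data frame of one row per replicate.
#' @param response name of the response column (final MSD).
#' @param strain name of the strain factor column.
#' @param others character vector of nuisance term names, fitted before
#'   strain.
#' @return list: `ratio`, `ss` (named sums of squares), `anova` table.
#' @export
variance_partition <- function(data, response = "msd_final",
                               strain = "strain", others = character(0)) {
  stopifnot(response %in% names(data), strain %in% names(data))
  if (length(unique(data[[strain]])) < 2) stop("need >= 2 strains")
  rhs <- paste(c(others, strain), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(coef(fit))))
    warning("rank-deficient design: some effects are aliased")
  # degenerate responses trigger spurious perfect-fit warnings in anova()
  a <- suppressWarnings(stats::anova(fit))
  ss <- a$`Sum Sq`
  terms <- rownames(a)
  sst1 <- ss[terms == strain]
  ssr <- ss[terms == "Residuals"]
  sst2 <- sum(ss[!(terms %in% c(strain, "Residuals"))])
  denom <- ssr + sst1 + sst2
  # guard against all-equal responses (all sums of squares are round-off)
  scale0 <- sum((data[[response]] - mean(data[[response]]))^2)
  if (denom <= 1e-12 * max(scale0, 1)) denom <- 0
  list(ratio = if (denom > 0) sst1 / denom else 0,
       ss = c(strain = sst1, other = sst2, residual = ssr),
       anova = a)
}
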