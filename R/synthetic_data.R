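#' Define a per-phase diffusive dispersal model
#'
#' Dispersal along the (quasi one-dimensional) corridor is modelled as a
#' reflected random walk in the signed arc-length coordinate `s`, with a
#' piecewise-constant diffusion coefficient: within phase `p` of duration
#' `duration[p]` minutes, each individual receives independent Gaussian
#' increments of variance `2 * D[p] * dt` per step. All individuals switch
#' phase synchronously (a deliberate simplification; see the package
#' vignette).
#'
#' @param duration phase durations (minutes).
#' @param D per-phase diffusion coefficients (mm^2/min).
#' @param n_individuals number of released individuals.
#' @param boundary only `"reflecting"` is supported (sealed tunnel tips).
#' @return an object of class `dispersal_model`.
#' @export
dispersal_model <- function(duration, D, n_individuals = 200,
                            boundary = "reflecting") {
  stopifnot(length(duration) == length(D), all(duration > 0), all(D >= 0),
            n_individuals >= 1)
  boundary <- match.arg(boundary, "reflecting")
  structure(list(duration = duration, D = D,
                 n_individuals = n_individuals, boundary = boundary),
            class = "dispersal_model")
}

#' Canonical dispersal dynamics presets
#'
#' Three qualitative dynamics of group dispersal over a six-hour assay,
#' expressed as phase schedules for [dispersal_model()]:
#' \describe{
#'   \item{type1}{strictly diffusive spread (one phase, constant D).}
#'   \item{type2}{a latency phase of slow spread followed by a sustained
#'     fast phase (break after 135 min).}
#'   \item{type3}{latency, then a fast phase, then the spread slows down
#'     again (breaks after 120 and 240 min).}
#' }
#' The diffusion coefficients (10; 2/20; 2/25/5 mm^2/min) are package
#' defaults chosen to give clearly separated phase slopes at a spread that
#' stays well inside a maze of a few metres over 360 minutes.
#'
#' @param type one of `"type1"`, `"type2"`, `"type3"`.
#' @param n_individuals number of released individuals.
#' @return a [dispersal_model()].
#' @export
dispersal_preset <- function(type = c("type1", "type2", "type3"),
                             n_individuals = 200) {
  type <- match.arg(type)
  switch(type,
    type1 = dispersal_model(360, 10, n_individuals),
    type2 = dispersal_model(c(135, 225), c(2, 20), n_individuals),
    type3 = dispersal_model(c(120, 120, 120), c(2, 25, 5), n_individuals)
  )
}

#' Simulate dispersal along the tunnel
#'
#' Runs the reflected per-phase random walk of a [dispersal_model()] in the
#' signed arc-length coordinate. All individuals start at `s = 0` (the
#' introduction point); positions are reflected at the tunnel tips
#' `+/- half_length`.
#'
#' @param model a [dispersal_model()].
#' @param half_length distance from the introduction point to either tunnel
#'   tip (mm); e.g. `geom$arc_length / 2`.
#' @param n_frames number of recorded frames (one per `dt`).
#' @param dt time step between frames (minutes).
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return an `n_individuals x n_frames` matrix of arc positions (mm), with
#'   attributes `t` (minutes) and `model`.
#' @export
simulate_linear_dispersal <- function(model, half_length, n_frames = 360,
                                      dt = 1, seed = .default_seed) {
  stopifnot(inherits(model, "dispersal_model"), half_length > 0)
  phase_of <- rep(seq_along(model$duration),
                  times = ceiling(model$duration / dt))
  if (length(phase_of) < n_frames)
    phase_of <- c(phase_of, rep(length(model$duration),
                                n_frames - length(phase_of)))
  n <- model$n_individuals
  out <- matrix(NA_real_, n, n_frames)
  with_seed(seed, {
    s <- rep(0, n)
    for (k in seq_len(n_frames)) {
      D <- model$D[phase_of[k]]
      if (D > 0) s <- s + rnorm(n, 0, sqrt(2 * D * dt))
      s <- reflect_positions(s, half_length)
      out[, k] <- s
    }
  })
  attr(out, "t") <- seq_len(n_frames) * dt
  attr(out, "model") <- model
  out
}

# fold positions into [-half, half] (reflecting boundaries)
reflect_positions <- function(s, half) {
  s <- (s + half) %% (4 * half)
  s <- ifelse(s > 2 * half, 4 * half - s, s)
  s - half
}

#' Embed arc positions into the plane
#'
#' Maps signed arc coordinates (and an optional perpendicular offset) to 2-D
#' plate coordinates via the maze centreline.
#'
#' @param geom a [maze_geometry].
#' @param s signed arc positions (mm).
#' @param perp perpendicular offsets (mm, positive to the left of travel).
#' @return an `n x 2` matrix of (x, y) in mm.
#' @export
arc_to_xy <- function(geom, s, perp = 0) {
  s <- pmin(pmax(s, min(geom$s)), max(geom$s))
  i <- findInterval(s, geom$s, all.inside = TRUE)
  t <- (s - geom$s[i]) / pmax(geom$s[i + 1] - geom$s[i], 1e-12)
  p <- geom$centerline[i, , drop = FALSE] * (1 - t) +
    geom$centerline[i + 1, , drop = FALSE] * t
  if (any(perp != 0)) {
    nrm <- centerline_normals(geom$centerline)
    nv <- nrm[i, , drop = FALSE] * (1 - t) + nrm[i + 1, , drop = FALSE] * t
    nv <- nv / sqrt(rowSums(nv^2))
    p <- p + perp * nv
  }
  p
}

#' Synthetic back-light illumination field
#'
#' Multiplicative illumination field (mean approximately 1) combining a
#' long-range horizontal gradient with a radial vignette, emulating a large
#' LED back-light panel that is slightly brighter at the centre. Folded along
#' a double spiral, the horizontal trend turns into periodic waves of the
#' along-path light profile rather than a trend in distance from the centre.
#'
#' @param nr,nc field dimensions (pixels).
#' @param gradient total relative drop from the centre to the horizontal
#'   edges (e.g. 0.14 for +/- 14 % waves along the path).
#' @param vignette relative drop from the centre to the corners.
#' @return an `nr x nc` numeric matrix.
#' @export
make_illumination_field <- function(nr, nc, gradient = 0.14,
                                    vignette = 0.05) {
  x <- (seq_len(nc) - 0.5) / nc - 0.5
  y <- (seq_len(nr) - 0.5) / nr - 0.5
  gx <- 1 - gradient * abs(2 * x)
  rho2 <- outer(y^2, x^2, "+") / 0.5
  (1 - vignette * rho2) * rep(gx, each = nr)
}

#' Render a ground-truthed back-lit image sequence
#'
#' Renders 8-bit grayscale frames of a back-lit maze: bright corridor floor,
#' darker walls, and each individual as a dark ellipse (aspect ratio 2.5,
#' major axis `insect_length`) oriented along the local corridor direction.
#' Individuals are placed at their simulated arc position with a uniform
#' lateral jitter of `+/- path_width/3`; a configurable fraction of
#' individual-frames is marked invisible (concealed behind walls) and not
#' drawn. Additive Gaussian pixel noise is applied per frame.
#'
#' Frames are generated lazily (`$frame(k)`) so that long sequences never
#' have to be held in memory; [analyze_sequence()] accepts the returned
#' object directly. With `dir` set, frames are also written as single-page
#' TIFF files `frame_0001.tif`, ...
#'
#' @param geom a [maze_geometry].
#' @param positions matrix of arc positions from
#'   [simulate_linear_dispersal()].
#' @param resolution pixels per mm.
#' @param insect_length body length (mm); must map to >= 2 px.
#' @param noise_sd additive Gaussian noise (grey levels).
#' @param floor_gray,wall_gray,blob_depth nominal grey levels of the lit
#'   floor, the walls, and the attenuation under an insect body.
#' @param illumination optional multiplicative field (matrix matching the
#'   frame size); default [make_illumination_field()].
#' @param hidden_fraction fraction of individual-frames concealed by walls.
#' @param seed RNG seed; per-frame noise streams are derived from it, so any
#'   frame can be rendered independently and reproducibly.
#' @param dir optional output directory for TIFF frames and ground truth.
#' @return an object of class `rendered_sequence`: list with `frame`
#'   (function of frame index), `n_frames`, `background` (noise-free
#'   background), `mask` (the [render_tunnel_mask()] raster),
#'   `ground_truth` (data frame: frame, id, s_mm, x_px, y_px, visible),
#'   `resolution`, and the render parameters.
#' @export
render_sequence <- function(geom, positions, resolution = 16,
                            insect_length = 0.5, noise_sd = 3,
                            floor_gray = 230, wall_gray = 140,
                            blob_depth = 110, illumination = NULL,
                            hidden_fraction = 0.01, seed = .default_seed,
                            dir = NULL) {
  a <- insect_length * resolution / 2
  if (2 * a < 2)
    stop("insect_length maps to fewer than 2 px at this resolution")
  b <- a / 2.5
  mask <- render_tunnel_mask(geom, resolution)
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (is.null(illumination)) illumination <- make_illumination_field(nr, nc)
  stopifnot(nrow(illumination) == nr, ncol(illumination) == nc)
  background <- illumination * ifelse(mask, floor_gray, wall_gray)

  n_ind <- nrow(positions)
  n_frames <- ncol(positions)
  gt <- with_seed(seed, {
    perp <- matrix(runif(n_ind * n_frames, -geom$path_width / 3,
                         geom$path_width / 3), n_ind, n_frames)
    vis <- matrix(runif(n_ind * n_frames) >= hidden_fraction, n_ind, n_frames)
    do.call(rbind, lapply(seq_len(n_frames), function(k) {
      xy <- arc_to_xy(geom, positions[, k], perp[, k])
      pxy <- mm_to_px(xy, geom, resolution)
      ang <- local_angle(geom, positions[, k])
      data.frame(frame = rep(k, n_ind), id = seq_len(n_ind),
                 s_mm = positions[, k],
                 x_px = pxy[, 1], y_px = pxy[, 2], angle = ang,
                 visible = vis[, k])
    }))
  })

  vis_by_frame <- split(gt[gt$visible, c("x_px", "y_px", "angle")],
                        gt$frame[gt$visible])
  frame_fun <- function(k) {
    stopifnot(k >= 1, k <= n_frames)
    g <- vis_by_frame[[as.character(k)]]
    blobs <- if (is.null(g)) matrix(0, 0, 3) else
      cbind(g$x_px, g$y_px, g$angle)
    img <- cpp_paint_blobs(background, blobs, a, b, blob_depth)
    with_seed(seed + 1000L + k, cpp_finalize_frame(img, noise_sd))
  }

  out <- structure(list(frame = frame_fun, n_frames = n_frames,
                        background = background, mask = mask,
                        ground_truth = gt, resolution = resolution,
                        insect_axes_px = c(a, b), noise_sd = noise_sd,
                        seed = seed),
                   class = "rendered_sequence")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_frames)) {
      tiff::writeTIFF(frame_fun(k) / 255,
                      file.path(dir, sprintf("frame_%04d.tif", k)),
                      bits.per.sample = 8L)
    }
    write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    out$dir <- dir
  }
  out
}

# local tangent angle (radians, image pixel coordinates: y downward)
local_angle <- function(geom, s) {
  s <- pmin(pmax(s, min(geom$s)), max(geom$s))
  i <- findInterval(s, geom$s, all.inside = TRUE)
  d <- geom$centerline[i + 1, , drop = FALSE] - geom$centerline[i, , drop = FALSE]
  atan2(-d[, 2], d[, 1])
}
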