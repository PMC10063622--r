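#' Temporal background estimation
#'
#' Estimates the still background of an image stack as the per-pixel
#' temporal median (robust to particles that keep moving) or mean.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param projection `"median"` (default) or `"mean"`.
#' @return a numeric matrix.
#' @export
estimate_background <- function(frames, projection = c("median", "mean")) {
  projection <- match.arg(projection)
  stopifnot(length(frames) >= 2)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  if (projection == "median") {
    cpp_stack_median(lapply(frames, function(f) {
      storage.mode(f) <- "double"
      f
    }))
  } else {
    Reduce(`+`, frames) / length(frames)
  }
}

#' Detect particles in one frame
#'
#' Computes the floating-point difference `background - frame` (insects are
#' darker than the back-lit floor, so they produce positive signal),
#' thresholds it, labels 8-connected components, discards components outside
#' `area_range`, and measures shape descriptors for the survivors:
#' * `circularity = 4 * pi * area / perimeter^2` (clipped to `[0, 1]`;
#'   perimeter by Moore chain-code tracing, diagonal steps weighted
#'   `sqrt(2)`),
#' * `solidity = area / convex hull area` (hull area counted in lattice
#'   pixels, so a convex particle scores 1),
#' * `aspect_ratio` = major/minor axis of the moments-equivalent ellipse
#'   (>= 1).
#'
#' Because detection operates on the difference image, it is invariant to
#' any global additive illumination change applied to both images.
#'
#' @param frame,background numeric matrices of identical size.
#' @param threshold grey-level threshold (> 0) on the difference image.
#' @param area_range `c(min, max)` particle area (px^2).
#' @return a data frame with one row per particle: `frame` (NA, filled by
#'   [analyze_sequence()]), `x`, `y` (centroid, continuous px), `area`,
#'   `circularity`, `solidity`, `aspect_ratio`.
#' @export
detect_frame <- function(frame, background, threshold,
                         area_range = c(2, 1e6)) {
  stopifnot(threshold > 0, all(dim(frame) == dim(background)))
  diffimg <- background - frame
  lab <- cpp_label8(diffimg >= threshold)
  st <- cpp_blob_stats(lab)
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      area = numeric(), circularity = numeric(),
                      solidity = numeric(), aspect_ratio = numeric())
  if (nrow(st) == 0) return(empty)
  keep <- st[, "area"] >= area_range[1] & st[, "area"] <= area_range[2]
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0) return(empty)
  # moments-equivalent ellipse axes
  tr <- st[, "mxx"] + st[, "myy"]
  det <- st[, "mxx"] * st[, "myy"] - st[, "mxy"]^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 1e-9)
  data.frame(
    frame = NA_integer_,
    x = st[, "cx"], y = st[, "cy"], area = st[, "area"],
    circularity = pmin(4 * pi * st[, "area"] / st[, "perimeter"]^2, 1),
    solidity = pmin(st[, "area"] / st[, "hull_px"], 1),
    aspect_ratio = sqrt(l1 / l2)
  )
}

#' Detect particles through an image sequence
#'
#' Runs the full detection pipeline over a sequence: frames are processed in
#' consecutive packs of `pack_size`, the background is re-estimated within
#' each pack (temporal median by default), and every frame is detected
#' against its pack's background. Deterministic: the output is one table of
#' detections in frame order.
#'
#' @param frames one of: a list of matrices, a character vector of TIFF file
#'   paths, a function `frame(k)`, or a `rendered_sequence` from
#'   [render_sequence()].
#' @param n_frames required when `frames` is a function.
#' @param pack_size frames per background pack (the last pack absorbs any
#'   remainder shorter than 2).
#' @param threshold,area_range,projection see [detect_frame()] and
#'   [estimate_background()].
#' @return a data frame of detections (see [detect_frame()]) with `frame`
#'   filled in.
#' @export
analyze_sequence <- function(frames, n_frames = NULL, pack_size = 60,
                             threshold = 50, area_range = c(2, 1e6),
                             projection = "median") {
  stopifnot(pack_size >= 2)
  if (inherits(frames, "rendered_sequence")) {
    n_frames <- frames$n_frames
    frames <- frames$frame
  }
  get_frame <- if (is.function(frames)) {
    stopifnot(!is.null(n_frames))
    frames
  } else if (is.character(frames)) {
    n_frames <- length(frames)
    paths <- frames
    function(k) read_frame_tiff(paths[k])
  } else {
    n_frames <- length(frames)
    lst <- frames
    function(k) lst[[k]]
  }
  starts <- seq(1, n_frames, by = pack_size)
  # a trailing pack of a single frame cannot support background estimation
  if (length(starts) > 1 && n_frames - starts[length(starts)] + 1 < 2)
    starts <- starts[-length(starts)]
  out <- vector("list", n_frames)
  for (st in starts) {
    en <- if (st == starts[length(starts)]) n_frames else
      min(st + pack_size - 1, n_frames)
    pack <- lapply(st:en, function(k) {
      f <- tryCatch(get_frame(k), error = function(e)
        stop(sprintf("failed to load frame %d: %s", k, conditionMessage(e))))
      storage.mode(f) <- "double"
      f
    })
    bg <- estimate_background(pack, projection)
    for (i in seq_along(pack)) {
      d <- detect_frame(pack[[i]], bg, threshold, area_range)
      if (nrow(d)) d$frame <- st + i - 1
      out[[st + i - 1]] <- d
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a grayscale TIFF frame
#'
#' Reads a single-page TIFF as a numeric matrix in grey levels 0..255
#' (16-bit input is rescaled).
#'
#' @param path TIFF file.
#' @return a numeric matrix.
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel
  img * 255
}

#' Light-intensity profile along the tunnel
#'
#' Samples an image along the path skeleton, converts pixel values to lux
#' through a linear calibration, and summarises the homogeneity of the
#' back-light along the corridor: mean intensity, maximal relative
#' deviation, and the Spearman correlation of |deviation| with |s| (a value
#' near 0 means lighting heterogeneity does not accumulate with distance
#' from the introduction point, the key property of the spiral folding).
#'
#' @param image numeric matrix (grey levels).
#' @param skeleton a [path_skeleton()].
#' @param lux_per_gray `c(gain, offset)`: `lux = gain * value + offset`,
#'   `gain > 0`.
#' @return a list: `profile` data frame (`s_mm`, `lux`), `mean_lux`,
#'   `max_rel_dev`, `spearman_abs_s`.
#' @export
light_profile_along_path <- function(image, skeleton,
                                     lux_per_gray = c(gain = 1, offset = 0)) {
  stopifnot(lux_per_gray[1] > 0)
  px <- skeleton$pixels
  val <- image[cbind(pmin(pmax(round(px$y + 0.5), 1), nrow(image)),
                     pmin(pmax(round(px$x + 0.5), 1), ncol(image)))]
  lux <- lux_per_gray[1] * val + lux_per_gray[2]
  m <- mean(lux)
  dev <- if (m != 0) abs(lux - m) / m else rep(0, length(lux))
  rho <- if (stats::sd(dev) > 0)
    cor(abs(px$s_mm), dev, method = "spearman") else 0
  list(profile = data.frame(s_mm = px$s_mm, lux = lux),
       mean_lux = m, max_rel_dev = max(dev), spearman_abs_s = rho)
}
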