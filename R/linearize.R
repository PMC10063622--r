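#' Skeletonize a tunnel mask
#'
#' Thins the binary corridor mask to a 1-px-wide 8-connected medial curve
#' (Zhang-Suen thinning) and removes short spur branches left by corner
#' artifacts, so that the result is a simple open curve with exactly two
#' endpoints (the tunnel tips).
#'
#' @param mask logical matrix (`TRUE` = tunnel), one connected component,
#'   e.g. from [render_tunnel_mask()].
#' @param prune_px remove spur branches shorter than this many pixels;
#'   default: the corridor width (estimated as mask area / skeleton length).
#' @return a logical skeleton matrix carrying the `resolution` attribute of
#'   the mask (if any).
#' @export
extract_skeleton <- function(mask, prune_px = NULL) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  if (!any(m)) stop("mask is empty")
  lab <- cpp_label8(m)
  if (attr(lab, "n") != 1)
    stop(sprintf("mask must be a single connected component (found %d)",
                 attr(lab, "n")))
  sk <- cpp_thin(m)
  if (is.null(prune_px))
    prune_px <- max(4L, as.integer(ceiling(sum(m) / max(sum(sk), 1))))
  sk <- cpp_prune_spurs(sk, as.integer(prune_px))
  attr(sk, "resolution") <- attr(mask, "resolution")
  sk
}

# skeleton endpoints: pixels whose foreground neighbours form one single
# connected component (curve interiors have two, junctions three or more)
skeleton_endpoints <- function(skel) {
  cls <- cpp_pixel_class(matrix(as.logical(skel), nrow(skel)))
  which(cls == 1L, arr.ind = TRUE)
}

#' Fragment the skeleton and order it from the centre
#'
#' Implements the skeleton-fragmentation mapping from pixels to a signed
#' curvilinear coordinate: the skeleton curve is cut wherever it crosses a
#' square grid of spacing `grid_spacing`, producing short ordered fragments;
#' the spiral centre is taken as the intersection of the diagonals of the
#' bounding rectangle of the mask (`plate_corners`), the fragment nearest
#' that point anchors `s = 0`, and cumulative signed arc length is assigned
#' walking outward along both arms (positive on the arm that leaves the
#' centre towards +x).
#'
#' Cumulative length is measured on chords between skeleton pixels about
#' half a grid cell apart, which suppresses the systematic overestimate of
#' naive 8-connected step counting on digitized curves.
#'
#' @param skel skeleton matrix from [extract_skeleton()].
#' @param grid_spacing grid spacing in px (>= 2); default half the corridor
#'   width.
#' @param plate_corners optional 4 x 2 matrix of rectangle corners
#'   (continuous px coordinates); default the full image rectangle.
#' @param resolution px/mm; default the `resolution` attribute of `skel`.
#' @return an object of class `path_skeleton`: list with `pixels`
#'   (data frame: `x`, `y` continuous px, `s_px`, `s_mm`, `fragment`),
#'   `fragments` (data frame: `fragment`, `arm`, `s_begin_mm`, `s_end_mm`,
#'   `n_px`), `center_px`, `grid_spacing`, `resolution`.
#' @export
fragment_and_order <- function(skel, grid_spacing = NULL,
                               plate_corners = NULL, resolution = NULL) {
  if (is.null(resolution)) resolution <- attr(skel, "resolution")
  if (is.null(resolution)) resolution <- 1
  ord <- cpp_walk_curve(skel)
  x <- ord[, 2] - 0.5
  y <- ord[, 1] - 0.5
  n <- length(x)
  if (is.null(grid_spacing)) {
    width_est <- attr(skel, "corridor_px")
    if (is.null(width_est)) width_est <- 10
    grid_spacing <- max(2L, round(width_est / 2))
  }
  stopifnot(grid_spacing >= 2)

  # chord-subsampled cumulative length (px)
  cs <- max(4L, round(grid_spacing / 2))
  anchors <- unique(c(seq(1L, n, by = cs), n))
  chord <- sqrt(diff(x[anchors])^2 + diff(y[anchors])^2)
  step <- sqrt(diff(x)^2 + diff(y)^2)  # naive steps, for within-chord spacing
  s_px <- numeric(n)
  acc <- 0
  for (k in seq_along(chord)) {
    i0 <- anchors[k]
    i1 <- anchors[k + 1]
    w <- cumsum(step[i0:(i1 - 1)])
    s_px[(i0 + 1):i1] <- acc + chord[k] * w / w[length(w)]
    acc <- acc + chord[k]
  }

  # centre from the diagonals of the bounding rectangle
  if (is.null(plate_corners)) {
    ctr <- c(ncol(skel) / 2, nrow(skel) / 2)
  } else {
    ctr <- diagonal_intersection(plate_corners)
  }
  i0 <- which.min((x - ctr[1])^2 + (y - ctr[2])^2)
  s_px <- s_px - s_px[i0]
  # positive arm = the arm leaving the centre towards +x
  probe <- min(n, i0 + max(grid_spacing, 4L))
  probe0 <- max(1L, i0 - max(grid_spacing, 4L))
  if (x[probe] - x[i0] < x[probe0] - x[i0]) s_px <- -s_px

  cell <- paste(floor(x / grid_spacing), floor(y / grid_spacing))
  frag <- cumsum(c(TRUE, cell[-1] != cell[-n]))
  pixels <- data.frame(x = x, y = y, s_px = s_px,
                       s_mm = s_px / resolution, fragment = frag)
  fr <- split(seq_len(n), frag)
  fragments <- data.frame(
    fragment = as.integer(names(fr)),
    arm = vapply(fr, function(i) {
      if (mean(pixels$s_mm[i]) >= 0) "right" else "left"
    }, ""),
    s_begin_mm = vapply(fr, function(i) min(pixels$s_mm[i]), 0),
    s_end_mm = vapply(fr, function(i) max(pixels$s_mm[i]), 0),
    n_px = lengths(fr)
  )
  rownames(fragments) <- NULL
  structure(list(pixels = pixels, fragments = fragments,
                 center_px = c(x[i0], y[i0]), grid_spacing = grid_spacing,
                 resolution = resolution),
            class = "path_skeleton")
}

diagonal_intersection <- function(corners) {
  # intersection of the two diagonals of a quadrilateral given as 4 corners
  # ordered around the rectangle
  p1 <- corners[1, ]; p3 <- corners[3, ]
  p2 <- corners[2, ]; p4 <- corners[4, ]
  d1 <- p3 - p1
  d2 <- p4 - p2
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

#' Build a path skeleton from a tunnel mask
#'
#' Convenience wrapper chaining [extract_skeleton()] and
#' [fragment_and_order()], with the grid spacing defaulting to half the
#' corridor width (estimated from the mask).
#'
#' @param mask a [render_tunnel_mask()] raster.
#' @param grid_spacing,plate_corners,prune_px see [fragment_and_order()] and
#'   [extract_skeleton()].
#' @return a `path_skeleton`.
#' @export
path_skeleton <- function(mask, grid_spacing = NULL, plate_corners = NULL,
                          prune_px = NULL) {
  sk0 <- cpp_thin(matrix(as.logical(mask), nrow(mask)))
  width_est <- sum(mask) / max(sum(sk0), 1)
  if (is.null(prune_px)) prune_px <- max(4L, 2L * round(width_est / 2))
  sk <- extract_skeleton(mask, prune_px = prune_px)
  attr(sk, "corridor_px") <- width_est
  fragment_and_order(sk, grid_spacing, plate_corners,
                     resolution = attr(mask, "resolution"))
}

#' @export
print.path_skeleton <- function(x, ...) {
  cat(sprintf(paste0("path skeleton: %d px in %d fragments, s in ",
                     "[%.1f, %.1f] mm, grid %d px, %.3g px/mm\n"),
              nrow(x$pixels), nrow(x$fragments), min(x$pixels$s_mm),
              max(x$pixels$s_mm), x$grid_spacing, x$resolution))
  invisible(x)
}

#' Project detections onto the path skeleton
#'
#' Orthogonally projects 2-D points onto the skeleton: for each point the
#' nearest skeleton pixel is found (bucketed search), the point is projected
#' onto the adjacent skeleton segments, and the signed curvilinear
#' coordinate is interpolated. Deterministic; points far from the tunnel
#' still project (they are removed later by the edge filter).
#'
#' @param points an `n x 2` matrix or data frame of (x, y) in continuous px
#'   coordinates (e.g. detection centroids).
#' @param path a `path_skeleton`.
#' @return a data frame: `s_mm` (signed arc coordinate), `perp_mm`
#'   (unsigned perpendicular offset), `fragment`.
#' @export
project_to_path <- function(points, path) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  px <- path$pixels
  if (nrow(pts) == 0)
    return(data.frame(s_mm = numeric(), perp_mm = numeric(),
                      fragment = integer()))
  ref <- cbind(px$x, px$y)
  nn <- cpp_nearest_point(pts, ref, cell = max(4, path$grid_spacing))
  idx <- as.integer(nn[, 1])
  n <- nrow(px)
  s_px <- px$s_px
  best_s <- s_px[idx]
  best_d <- nn[, 2]
  for (nb in c(-1L, 1L)) {
    j <- idx + nb
    ok <- j >= 1 & j <= n
    a <- ref[idx[ok], , drop = FALSE]
    b <- ref[pmin(pmax(j[ok], 1), n), , drop = FALSE]
    ab <- b - a
    len2 <- rowSums(ab^2)
    t <- ((pts[ok, 1] - a[, 1]) * ab[, 1] +
            (pts[ok, 2] - a[, 2]) * ab[, 2]) / pmax(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    proj <- a + t * ab
    d <- sqrt((pts[ok, 1] - proj[, 1])^2 + (pts[ok, 2] - proj[, 2])^2)
    s_cand <- s_px[idx[ok]] + t * (s_px[pmin(pmax(j[ok], 1), n)] -
                                     s_px[idx[ok]])
    upd <- d < best_d[ok] - 1e-12 |
      (abs(d - best_d[ok]) <= 1e-12 & abs(s_cand) < abs(best_s[ok]))
    bi <- which(ok)[upd]
    best_d[bi] <- d[upd]
    best_s[bi] <- s_cand[upd]
  }
  data.frame(s_mm = best_s / path$resolution,
             perp_mm = best_d / path$resolution,
             fragment = px$fragment[idx])
}

#' Serialize a path skeleton
#'
#' Writes the fragment table as CSV and the conventions (centre, grid
#' spacing, resolution, sign convention) as JSON.
#'
#' @param path a `path_skeleton`.
#' @param csv,json output files (either may be `NULL` to skip).
#' @return invisibly, a list of the files written.
#' @export
write_path_skeleton <- function(path, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(path$fragments, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(center_px = path$center_px,
                              grid_spacing = path$grid_spacing,
                              resolution = path$resolution,
                              sign_convention = "arm leaving centre towards +x is positive"),
                         json, digits = NA, auto_unbox = TRUE)
  }
  invisible(list(csv = csv, json = json))
}
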