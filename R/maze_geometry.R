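#' Generate a double-spiral maze geometry
#'
#' Builds the centreline and wall outline of a two-armed spiral corridor: two
#' interleaved Archimedean spirals, point-symmetric about the arena centre and
#' joined there by a smooth S-curve, so that individuals released at the
#' centre experience an identical corridor whichever direction they take.
#' The corridor has constant width and the radial pitch between successive
#' corridor passes is `path_width + wall_width`.
#'
#' The default profile is calibrated so that a 10 mm corridor wrapped in a
#' 440 x 330 mm plate reaches a total centreline length of 5.75 m
#' (`wall_width = 2.5`, `n_turns_per_arm = 5.088`, frozen constants).
#'
#' The centreline is parameterised by signed arc length `s` (mm), with
#' `s = 0` at the introduction point (the plate centre), positive on the arm
#' that leaves the centre towards +x and negative on the other arm.
#'
#' @param plate_width,plate_height outer plate dimensions (mm).
#' @param path_width corridor width (mm).
#' @param wall_width nominal wall thickness between corridor passes (mm).
#' @param wall_height wall height (mm); used by the occlusion model.
#' @param n_turns_per_arm number of spiral turns per arm (may be fractional;
#'   the spiral arm simply stops partway around its last turn).
#' @param handedness `"levogyrous"` (arms turn counter-clockwise outward) or
#'   `"dextrogyrous"` (the mirror image).
#' @param margin minimal clearance between the outermost wall and the plate
#'   edge (mm).
#' @param ds sampling step of the centreline polyline (mm).
#'
#' @return An object of class `maze_geometry`: a list with the plate and
#'   corridor dimensions, the centreline (`n x 2` matrix, mm, origin at the
#'   plate centre, y up), the signed arc-length vector `s` (mm), the total
#'   `arc_length` (mm), and `wall_polygons` (closed polygons flanking the
#'   corridor, mm).
#' @examples
#' geom <- generate_double_spiral()
#' geom$arc_length / 1000  # total corridor length in metres
#' @export
generate_double_spiral <- function(plate_width = 440, plate_height = 330,
                                   path_width = 10, wall_width = 2.5,
                                   wall_height = 5,
                                   n_turns_per_arm = 5.088,
                                   handedness = c("levogyrous", "dextrogyrous"),
                                   margin = 2, ds = 0.5) {
  handedness <- match.arg(handedness)
  stopifnot(path_width > 0, wall_width > 0, n_turns_per_arm >= 0, ds > 0)
  pitch <- path_width + wall_width          # radial spacing of corridor passes
  # the spiral arms start two pitches out, so the central S-curve (radius
  # r0/2 = pitch) never lets the corridor pinch against itself
  r0 <- 2 * pitch
  b <- pitch / pi                           # dr/dtheta (per-arm pitch 2*pitch)
  r_max <- r0 + b * 2 * pi * n_turns_per_arm
  outer_extent <- r_max + path_width / 2 + wall_width
  if (2 * (outer_extent + margin) > min(plate_width, plate_height)) {
    stop(sprintf(paste0("double spiral does not fit the plate: outer radius ",
                        "%.1f mm + %.1f mm margin exceeds half the plate ",
                        "height (%.1f mm); reduce n_turns_per_arm, ",
                        "path_width or wall_width"),
                 outer_extent, margin, min(plate_width, plate_height) / 2))
  }

  # Right half of the path, from the introduction point outward:
  # lower semicircle of the S-curve, then spiral arm A.
  half <- r0 / 2
  t_s <- seq(-pi, 0, length.out = max(16, ceiling(pi * half / ds)))
  s_curve <- cbind(half + half * cos(t_s), half * sin(t_s))
  theta_end <- 2 * pi * n_turns_per_arm
  pts <- list(s_curve)
  if (theta_end > 0) {
    # adaptive theta stepping for near-uniform arc sampling
    th <- 0
    arm <- matrix(NA_real_, nrow = ceiling(arc_length_spiral(r0, b, theta_end) /
                                             ds) + 8, ncol = 2)
    k <- 0
    while (th < theta_end) {
      r <- r0 + b * th
      k <- k + 1
      arm[k, ] <- c(r * cos(th), r * sin(th))
      th <- th + ds / sqrt(r^2 + b^2)
    }
    r <- r0 + b * theta_end
    arm[k + 1, ] <- c(r * cos(theta_end), r * sin(theta_end))
    pts$arm <- arm[seq_len(k + 1), , drop = FALSE]
  }
  right <- do.call(rbind, pts)
  right <- right[c(TRUE, rowSums(abs(diff(right))) > 1e-9), , drop = FALSE]

  # the double spiral is the union of the right half and its point reflection
  left <- -right[rev(seq_len(nrow(right))), , drop = FALSE]
  centerline <- rbind(left[-nrow(left), , drop = FALSE], right)
  if (handedness == "dextrogyrous") centerline[, 1] <- -centerline[, 1]

  seg <- sqrt(rowSums(diff(centerline)^2))
  cum <- c(0, cumsum(seg))
  i0 <- which.min(rowSums(centerline^2))   # introduction point (origin)
  s <- cum - cum[i0]
  geom <- structure(list(
    plate_width = plate_width, plate_height = plate_height,
    path_width = path_width, wall_width = wall_width,
    wall_height = wall_height, n_turns_per_arm = n_turns_per_arm,
    handedness = handedness, pitch = pitch, r0 = r0,
    centerline = centerline, s = s, arc_length = sum(seg)
  ), class = "maze_geometry")
  geom$wall_polygons <- wall_bands(geom)
  geom
}

#' Arc length of an Archimedean spiral segment
#'
#' Closed-form arc length of `r(theta) = a + b * theta` from 0 to `theta`,
#' the building block used to size spiral arms.
#'
#' @param a,b spiral parameters (mm, mm/radian).
#' @param theta end angle (radians).
#' @return arc length (same units as `a`).
#' @export
arc_length_spiral <- function(a, b, theta) {
  if (b == 0) return(a * theta)
  f <- function(r) (r * sqrt(r^2 + b^2) + b^2 * asinh(r / b)) / (2 * b)
  f(a + b * theta) - f(a)
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf(paste0("double-spiral maze: plate %g x %g mm, corridor ",
                     "%g mm wide, walls %g mm,\n  %.3f turns/arm (%s), ",
                     "centreline length %.1f mm (%.2f m)\n"),
              x$plate_width, x$plate_height, x$path_width, x$wall_width,
              x$n_turns_per_arm, x$handedness, x$arc_length,
              x$arc_length / 1000))
  invisible(x)
}

#' Mirror a maze geometry
#'
#' Reflects the geometry about the vertical axis, turning a levogyrous maze
#' into a dextrogyrous one (and vice versa) with identical arc lengths.
#'
#' @param geom a [maze_geometry].
#' @return the mirrored `maze_geometry`.
#' @export
mirror_maze <- function(geom) {
  geom$centerline[, 1] <- -geom$centerline[, 1]
  geom$wall_polygons <- lapply(geom$wall_polygons, function(p) {
    p[, 1] <- -p[, 1]
    p
  })
  geom$handedness <- setdiff(c("levogyrous", "dextrogyrous"), geom$handedness)
  geom
}

# unit normals of the centreline polyline (left of the travel direction)
centerline_normals <- function(centerline) {
  n <- nrow(centerline)
  d <- rbind(centerline[2, ] - centerline[1, ],
             centerline[3:n, , drop = FALSE] -
               centerline[1:(n - 2), , drop = FALSE],
             centerline[n, ] - centerline[n - 1, ])
  len <- sqrt(rowSums(d^2))
  cbind(-d[, 2] / len, d[, 1] / len)
}

# offset polyline at signed distance d (positive = left of travel)
offset_curve <- function(centerline, d) {
  centerline + d * centerline_normals(centerline)
}

# closed polygon outlining the corridor (the laser-cut line)
tunnel_outline <- function(geom) {
  hw <- geom$path_width / 2
  lft <- offset_curve(geom$centerline, hw)
  rgt <- offset_curve(geom$centerline, -hw)
  n <- nrow(geom$centerline)
  cap <- function(i, from) {
    # semicircular end cap around centreline point i, sweeping half a turn
    # clockwise from `from` (through the outward tangent direction)
    c0 <- geom$centerline[i, ]
    a0 <- atan2(from[2] - c0[2], from[1] - c0[1])
    aa <- seq(a0, a0 - pi, length.out = 9)[-c(1, 9)]
    cbind(c0[1] + hw * cos(aa), c0[2] + hw * sin(aa))
  }
  rbind(lft,
        cap(n, lft[n, ]),
        rgt[rev(seq_len(n)), , drop = FALSE],
        cap(1, rgt[1, ]))
}

# two closed wall bands flanking the corridor, each wall_width/2 thick so
# that bands of adjacent corridor passes tile the inter-pass gap without
# overlapping
wall_bands <- function(geom) {
  hw <- geom$path_width / 2
  wt <- geom$wall_width / 2
  band <- function(side) {
    inner <- offset_curve(geom$centerline, side * hw)
    outer <- offset_curve(geom$centerline, side * (hw + wt))
    rbind(inner, outer[rev(seq_len(nrow(outer))), , drop = FALSE])
  }
  list(left = band(1), right = band(-1))
}

#' Rasterize the tunnel floor of a maze
#'
#' Scan-converts the corridor outline into a binary mask (`TRUE` = tunnel
#' floor). Pixel `(i, j)` of the matrix (row `i` from the top) covers the
#' physical square centred at
#' `x = -plate_width/2 + (j - 0.5)/resolution` mm,
#' `y =  plate_height/2 - (i - 0.5)/resolution` mm.
#'
#' @param geom a [maze_geometry].
#' @param resolution pixels per millimetre.
#' @return a logical matrix of class `tunnel_mask` with attributes
#'   `resolution` (px/mm) and `plate` (mm).
#' @export
render_tunnel_mask <- function(geom, resolution) {
  stopifnot(resolution > 0)
  nr <- round(geom$plate_height * resolution)
  nc <- round(geom$plate_width * resolution)
  poly <- mm_to_px(tunnel_outline(geom), geom, resolution)
  m <- cpp_fill_polygons(nr, nc, list(poly))
  # the offset outline can self-touch at the tip caps, leaving stray
  # single-pixel slivers under even-odd filling; keep the main component
  lab <- cpp_label8(m)
  if (attr(lab, "n") > 1) {
    main <- which.max(tabulate(lab[lab > 0], attr(lab, "n")))
    m <- matrix(lab == main, nr, nc)
  }
  structure(m, resolution = resolution,
            plate = c(geom$plate_width, geom$plate_height),
            class = c("tunnel_mask", class(m)))
}

# mm (origin at plate centre, y up) -> continuous pixel coordinates (x, y)
mm_to_px <- function(xy, geom, resolution) {
  cbind((xy[, 1] + geom$plate_width / 2) * resolution,
        (geom$plate_height / 2 - xy[, 2]) * resolution)
}

px_to_mm <- function(xy, geom, resolution) {
  cbind(xy[, 1] / resolution - geom$plate_width / 2,
        geom$plate_height / 2 - xy[, 2] / resolution)
}

#' Fraction of tunnel floor hidden from an overhead camera
#'
#' Central-projection occlusion model: a vertical wall of height `h` whose
#' top edge lies at lateral distance `r` from the optical axis hides, on its
#' far side, a floor strip of radial width `r * h / (camera_height - h)`.
#' Every corridor pass is therefore shadowed along the wall on its
#' axis-facing side; the strip is clipped to the corridor width.
#'
#' The model integrates the strip width along the centreline and reports the
#' hidden fraction of the floor area, its complement (the monitored
#' fraction), per-bin fractions along `|s|`, and the correlation of the
#' per-bin occlusion with distance from the introduction point (a flat
#' profile means image coverage does not degrade along the tunnel).
#'
#' `object_diameter` optionally reduces every strip by the body size of the
#' tracked organism, giving the fraction of floor on which such an organism
#' could be hidden *entirely* (an organism wider than the local strip always
#' has a visible part).
#'
#' @param geom a [maze_geometry].
#' @param wall_height wall height (mm); defaults to the geometry's value.
#' @param camera_height camera (pinhole) height above the floor (mm).
#' @param optical_axis (x, y) of the optical axis in mm; default the plate
#'   centre.
#' @param object_diameter organism body diameter (mm); 0 = bare floor.
#' @param n_bins number of `|s|` bins for the coverage profile.
#' @return a list: `fraction` (hidden), `monitored`, `per_bin` data frame
#'   (`s_mid`, `fraction`), and `cor_abs_s`.
#' @export
occluded_floor_fraction <- function(geom, wall_height = geom$wall_height,
                                    camera_height = 700,
                                    optical_axis = c(0, 0),
                                    object_diameter = 0, n_bins = 20) {
  if (camera_height <= wall_height)
    stop("camera_height must exceed wall_height")
  cl <- geom$centerline
  n <- nrow(cl)
  nrm <- centerline_normals(cl)
  seg <- sqrt(rowSums(diff(cl)^2))
  dl <- c(seg[1] / 2, (seg[-1] + seg[-length(seg)]) / 2, seg[length(seg)] / 2)
  hw <- geom$path_width / 2
  if (wall_height <= 0) {
    width <- rep(0, n)
  } else {
    rel <- cbind(cl[, 1] - optical_axis[1], cl[, 2] - optical_axis[2])
    # flanking boundary point closer to the optical axis
    b1 <- cl + hw * nrm
    b2 <- cl - hw * nrm
    d1 <- sqrt((b1[, 1] - optical_axis[1])^2 + (b1[, 2] - optical_axis[2])^2)
    d2 <- sqrt((b2[, 1] - optical_axis[1])^2 + (b2[, 2] - optical_axis[2])^2)
    inner1 <- d1 < d2
    rb <- ifelse(inner1, d1, d2)
    bx <- ifelse(inner1, b1[, 1], b2[, 1]) - optical_axis[1]
    by <- ifelse(inner1, b1[, 2], b2[, 2]) - optical_axis[2]
    # radial shadow width, projected across the corridor
    w_rad <- rb * wall_height / (camera_height - wall_height)
    w_rad <- pmax(w_rad - object_diameter, 0)
    ub <- sqrt(bx^2 + by^2)
    cosf <- ifelse(ub > 0, abs(bx / ub * nrm[, 1] + by / ub * nrm[, 2]), 0)
    width <- pmin(w_rad * cosf, geom$path_width)
  }
  occ_area <- sum(width * dl)
  floor_area <- sum(geom$path_width * dl)
  bins <- cut(abs(geom$s), breaks = n_bins)
  per_bin <- data.frame(
    s_mid = tapply(abs(geom$s), bins, mean),
    fraction = tapply(width * dl, bins, sum) /
      tapply(geom$path_width * dl, bins, sum)
  )
  rownames(per_bin) <- NULL
  ok <- complete.cases(per_bin)
  list(fraction = occ_area / floor_area,
       monitored = 1 - occ_area / floor_area,
       per_bin = per_bin[ok, ],
       cor_abs_s = if (sum(ok) > 2 && stats::sd(per_bin$fraction[ok]) > 0)
         cor(per_bin$s_mid[ok], per_bin$fraction[ok]) else 0)
}

#' Export a maze drawing as SVG
#'
#' Writes the plate outline and the corridor cut line (plus wall bands, for
#' inspection) as an SVG drawing in millimetre user units, suitable as a
#' starting point for laser cutting.
#'
#' @param geom a [maze_geometry].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_maze_svg <- function(geom, path) {
  w <- geom$plate_width
  h <- geom$plate_height
  to_svg <- function(xy) {
    paste(sprintf("%.3f,%.3f", xy[, 1] + w / 2, h / 2 - xy[, 2]),
          collapse = " ")
  }
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%gmm" ',
                   'height="%gmm" viewBox="0 0 %g %g">'), w, h, w, h),
    sprintf(paste0('<rect x="0" y="0" width="%g" height="%g" fill="none" ',
                   'stroke="black" stroke-width="0.2"/>'), w, h),
    sprintf(paste0('<polygon points="%s" fill="none" stroke="red" ',
                   'stroke-width="0.2"/>'), to_svg(tunnel_outline(geom))),
    vapply(geom$wall_polygons, function(p) {
      sprintf(paste0('<polygon points="%s" fill="none" stroke="grey" ',
                     'stroke-width="0.1"/>'), to_svg(p))
    }, ""),
    "</svg>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a maze geometry to JSON
#'
#' @param geom a [maze_geometry].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
maze_to_json <- function(geom, path) {
  x <- unclass(geom)
  x$centerline <- unname(x$centerline)
  x$wall_polygons <- lapply(x$wall_polygons, unname)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a maze geometry from JSON
#'
#' @param path file written by [maze_to_json()].
#' @return a [maze_geometry].
#' @export
maze_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$centerline <- as.matrix(x$centerline)
  x$wall_polygons <- lapply(x$wall_polygons, as.matrix)
  structure(x, class = "maze_geometry")
}
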