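test_that("default double spiral reproduces the device dimensions", {
  geom <- generate_double_spiral()
  expect_equal(geom$arc_length, 5750, tolerance = 0.02)
  expect_equal(geom$plate_width, 440)
  expect_equal(geom$plate_height, 330)
  # fits inside the plate
  r <- sqrt(rowSums(geom$centerline^2))
  expect_lt(max(r) + geom$path_width / 2 + geom$wall_width,
            min(geom$plate_width, geom$plate_height) / 2)
  # both arms have equal arc length (0.5 %)
  expect_equal(max(geom$s), -min(geom$s), tolerance = 0.005)
})

test_that("mirroring flips handedness and preserves arc lengths", {
  geom <- generate_double_spiral(n_turns_per_arm = 2)
  mir <- mirror_maze(geom)
  expect_equal(mir$handedness, "dextrogyrous")
  expect_equal(mir$arc_length, geom$arc_length)
  expect_equal(mir$centerline[, 1], -geom$centerline[, 1])
  dex <- generate_double_spiral(n_turns_per_arm = 2,
                                handedness = "dextrogyrous")
  expect_equal(dex$arc_length, geom$arc_length)
})

test_that("the centreline sits half a corridor width from both walls", {
  geom <- fx_demo_maze()
  sample_s <- seq(2 * geom$pitch, max(geom$s) - 2 * geom$pitch, by = 17)
  pts <- arc_to_xy(geom, c(sample_s, -sample_s))
  for (side in geom$wall_polygons) {
    nn <- cpp_nearest_point(pts, side, cell = 5)
    # nearest wall-band vertex: bands are the left and right flanks, so the
    # distance to the closer flank must be path_width/2 within 5 %
    expect_lt(max(abs(nn[, 2] - geom$path_width / 2)) /
                geom$path_width, 0.05)
  }
})

test_that("wall bands stay inside the plate and do not cross each other", {
  geom <- fx_demo_maze()
  for (p in geom$wall_polygons) {
    expect_true(all(abs(p[, 1]) <= geom$plate_width / 2))
    expect_true(all(abs(p[, 2]) <= geom$plate_height / 2))
  }
  # the two bands flank opposite sides of the corridor: every vertex of one
  # band is at least one corridor width away from the other band's
  # centre-offset, sampled coarsely
  a <- geom$wall_polygons[[1]][seq(1, nrow(geom$wall_polygons[[1]]), 40), ]
  nn <- cpp_nearest_point(a, geom$centerline, cell = 5)
  expect_true(all(nn[, 2] >= geom$path_width / 2 - 1e-6))
})

test_that("degenerate and invalid geometries are handled", {
  g0 <- generate_double_spiral(n_turns_per_arm = 0)
  expect_equal(max(g0$s), -min(g0$s), tolerance = 1e-6)
  expect_error(generate_double_spiral(n_turns_per_arm = 50),
               "does not fit")
})

test_that("spiral arc length matches numeric quadrature", {
  a <- 12.5
  b <- 4
  quad <- integrate(function(th) sqrt((a + b * th)^2 + b^2), 0, 2 * pi,
                    rel.tol = 1e-10)$value
  expect_equal(arc_length_spiral(a, b, 2 * pi), quad, tolerance = 1e-3)
  # arc length grows strictly with the number of turns
  lens <- vapply(c(0.5, 1, 1.5, 2), function(n)
    generate_double_spiral(n_turns_per_arm = n)$arc_length, 0)
  expect_true(all(diff(lens) > 0))
})

test_that("tunnel mask area matches the corridor area", {
  st <- straight_geometry(100, 10)
  m <- render_tunnel_mask(st, 10)
  # corridor rectangle plus the two semicircular end caps
  expect_equal(sum(m), (100 * 10 + pi * 25) * 10^2, tolerance = 0.03)

  geom <- fx_demo_maze()
  md <- fx_demo_mask(2.5)
  expect_equal(sum(md), geom$arc_length * geom$path_width * 2.5^2,
               tolerance = 0.03)
  # shoelace area of the outline polygon as an independent oracle
  ol <- spiralmaze:::tunnel_outline(geom)
  n <- nrow(ol)
  shoelace <- abs(sum(ol[, 1] * ol[c(2:n, 1), 2] -
                        ol[c(2:n, 1), 1] * ol[, 2])) / 2
  expect_equal(sum(md) / 2.5^2, shoelace, tolerance = 0.03)
})

test_that("masks are a single 8-connected component", {
  lab <- cpp_label8(matrix(as.logical(fx_demo_mask(2.5)),
                           nrow(fx_demo_mask(2.5))))
  expect_identical(attr(lab, "n"), 1L)
  # the full-size device at the nominal imaging resolution
  big <- render_tunnel_mask(generate_double_spiral(), 16)
  lab16 <- cpp_label8(matrix(as.logical(big), nrow(big)))
  expect_identical(attr(lab16, "n"), 1L)
})

test_that("occlusion model behaves like central projection", {
  geom <- fx_demo_maze()
  expect_equal(occluded_floor_fraction(geom, wall_height = 0)$fraction, 0)
  expect_error(occluded_floor_fraction(geom, wall_height = 10,
                                       camera_height = 5))
  o <- occluded_floor_fraction(geom, 5, 700)
  expect_true(o$fraction > 0 && o$fraction < 1)
  expect_equal(o$fraction + o$monitored, 1)
  # monotone in wall height, decreasing in camera height
  expect_lt(occluded_floor_fraction(geom, 2, 700)$fraction, o$fraction)
  expect_lt(occluded_floor_fraction(geom, 5, 1400)$fraction, o$fraction)
  # analytic strip model vs pixel-level ray casting (0.5 percentage points)
  rc <- raycast_occlusion_oracle(render_tunnel_mask(geom, 3), 5, 700)
  expect_lt(abs(o$fraction - rc), 0.005)
  # a larger object cannot be hidden on more floor than a point
  o2 <- occluded_floor_fraction(geom, 5, 700, object_diameter = 0.5)
  expect_lt(o2$fraction, o$fraction)
})

test_that("geometry serialization round-trips and SVG export is valid", {
  geom <- generate_double_spiral(n_turns_per_arm = 1.5)
  js <- file.path(tempdir(), "maze.json")
  maze_to_json(geom, js)
  back <- maze_from_json(js)
  expect_equal(back$arc_length, geom$arc_length)
  expect_equal(back$centerline, unname(geom$centerline))
  svg <- file.path(tempdir(), "maze.svg")
  export_maze_svg(geom, svg)
  txt <- readLines(svg)
  expect_true(grepl("<svg", txt[1]))
  expect_true(any(grepl("polygon", txt)))
  unlink(c(js, svg))
})
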