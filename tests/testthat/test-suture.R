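test_that("Koch generator follows the 4^n growth law", {
  expect_equal(nrow(koch_curve(0, 1, 1, smooth = FALSE)$points), 1L)  # one segment
  expect_equal(nrow(koch_curve(1, 1, 1, smooth = FALSE)$points), 4L)
  k <- koch_curve(3, 4, 1.8, smooth = FALSE)
  expect_equal(k$meta$n_segments, 4L * 4L^3)
  expect_equal(nrow(k$points), 256L)  # open storage: one vertex per segment
  expect_error(koch_curve(-1, 4, 1), "iterations")
  expect_error(koch_curve(2, 4, -1), "amplitude")
})

test_that("Koch curves scale to the requested amplitude and smooth cleanly", {
  for (sm in c(FALSE, TRUE)) {
    k <- koch_curve(2, 4, 1.822, smooth = sm)
    expect_equal(diff(range(k$points[, "y"])), 1.822, tolerance = 1e-12)
  }
  # smoothing retains the generator topology (fixed points per segment)
  k <- koch_curve(2, 4, 1, smooth = TRUE, points_per_segment = 3L)
  expect_equal(nrow(k$points), 3L * 64L)
})

test_that("lobate curves have exactly n lobes and bilateral symmetry", {
  for (n in 3:6) {
    lc <- lobate_curve(n, 2)
    expect_equal(count_local_minima(lc), n)
  }
  lc <- lobate_curve(4, 2, n_points = 480L)
  y <- lc$points[, "y"]
  # mirror of the half-curve reproduces the whole: y(x) == y(1 - x)
  expect_equal(y[-1], rev(y[-1]), tolerance = 1e-9)
  # near-flat limit: axial variation shrinks with amplitude
  expect_lt(diff(range(lobate_curve(4, 1e-9)$points[, "y"])), 1e-8)
  expect_error(lobate_curve(4, 0), "amplitude")
})

test_that("wrapping puts every vertex on the cylinder and closes the curve", {
  for (curve in list(lobate_curve(6, 1.822), koch_curve(2, 4, 1.822))) {
    s <- wrap_on_cylinder(curve, 9.11, axial_center = 3)
    d <- sqrt(s$points[, 1]^2 + s$points[, 2]^2)
    expect_lt(max(abs(d - 9.11)), 1e-6)
    expect_equal(s$points[1, ], s$points[nrow(s$points), ])
    expect_equal(mean(s$points[, 3]), 3, tolerance = 0.2)
  }
  # flat curve wraps to a planar circle at the axial centre
  x <- (0:95) / 96
  flat <- phragmoFEM:::new_planar_curve(cbind(x = x, y = rep(0, 96)))
  c0 <- wrap_on_cylinder(flat, 5, axial_center = 1)
  expect_equal(range(c0$points[, 3]), c(1, 1))
  # arc length exceeds the flat circumference once there is amplitude
  expect_gt(suture_arc_length(wrap_on_cylinder(lobate_curve(6, 1.822), 9.11)),
            suture_arc_length(c0) / (2 * pi * 5) * (2 * pi * 9.11))
})

test_that("generated suture curves are simple on the unrolled cylinder", {
  curves <- list(lobate_curve(3, 1.822), lobate_curve(6, 1.822),
                 koch_curve(1, 4, 1.822), koch_curve(3, 4, 1.822))
  for (cu in curves) {
    s <- wrap_on_cylinder(cu, 9.11)
    pts <- phragmoFEM:::unroll_suture(s)
    expect_true(phragmoFEM:::polyline_is_simple(pts, 2 * pi * 9.11))
  }
})

test_that("max_safe_offset reproduces the thin-Koch-septum constraint", {
  x <- (0:95) / 96
  flat <- phragmoFEM:::new_planar_curve(cbind(x = x, y = rep(0, 96)))
  circ <- wrap_on_cylinder(flat, 9.11)
  expect_gte(max_safe_offset(circ), 9.11)  # straight line never collides

  koch3 <- wrap_on_cylinder(koch_curve(3, 4, 1.822), 9.11)
  lob6 <- wrap_on_cylinder(lobate_curve(6, 1.822), 9.11)
  off_k <- max_safe_offset(koch3)
  off_l <- max_safe_offset(lob6)
  expect_lt(off_k, off_l)          # Koch frills collide far earlier
  expect_gt(off_k, 0.04 / 2)       # 0.04 mm septa are buildable
  expect_lt(off_k, 0.4 / 2)        # 0.4 mm septa self-intersect
  # bisection output: just-simple below, colliding above
  period <- 2 * pi * 9.11
  pts <- phragmoFEM:::unroll_suture(koch3)
  ok <- function(d) {
    phragmoFEM:::polyline_is_simple(
      phragmoFEM:::offset_polyline(pts, d, period), period) &&
      phragmoFEM:::polyline_is_simple(
        phragmoFEM:::offset_polyline(pts, -d, period), period)
  }
  expect_true(ok(0.98 * off_k))
  expect_false(ok(1.02 * off_k + 1e-3))
})

test_that("suture CSV round-trips", {
  s <- wrap_on_cylinder(lobate_curve(4, 1.5), 9.11, axial_center = 2)
  path <- tempfile(fileext = ".csv")
  write_suture_csv(s, path)
  s2 <- read_suture_csv(path)
  expect_equal(s2$points, s$points, ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(s2$radius, 9.11)
  expect_equal(s2$axial_center, 2)
})
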