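#' @useDynLib phragmoFEM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats splinefun approx lm coef predict sd setNames quantile
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Planar suture-line curves
#
# A planar curve is an ordered polyline (x, y): x is the arc position around
# the shell tube rescaled to [0, 1], y the axial (apical) amplitude in mm.
# Lobate curves are single-valued in x; Koch curves of iteration >= 2 have
# overhangs, so the polyline is ordered by traversal, not by x.
# ---------------------------------------------------------------------------

new_planar_curve <- function(points, periodic = TRUE, meta = list()) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  colnames(points) <- c("x", "y")
  if (nrow(points) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-14)
    points <- points[keep, , drop = FALSE]
  }
  structure(list(points = points, periodic = periodic, meta = meta),
            class = "planar_curve")
}

#' @export
print.planar_curve <- function(x, ...) {
  cat(sprintf("<planar_curve: %d vertices, %s, y-range [%.3g, %.3g]>\n",
              nrow(x$points), if (x$periodic) "periodic" else "open",
              min(x$points[, "y"]), max(x$points[, "y"])))
  invisible(x)
}

# one application of the classic triadic Koch generator to an open polyline;
# the bump apex points toward -y for a left-to-right baseline (apical lobes)
koch_iterate_once <- function(pts) {
  n <- nrow(pts) - 1L
  p <- pts[seq_len(n), , drop = FALSE]
  q <- pts[seq_len(n) + 1L, , drop = FALSE]
  d <- q - p
  a <- p + d / 3
  b <- p + 2 * d / 3
  mid <- p + d / 2
  # rotate the segment direction by -90 degrees: (dx, dy) -> (dy, -dx)
  perp <- cbind(d[, 2], -d[, 1]) / 3 * (sqrt(3) / 2)
  apex <- mid + perp
  out <- matrix(0, nrow = 4L * n + 1L, ncol = 2)
  idx <- (seq_len(n) - 1L) * 4L
  out[idx + 1L, ] <- p
  out[idx + 2L, ] <- a
  out[idx + 3L, ] <- apex
  out[idx + 4L, ] <- b
  out[4L * n + 1L, ] <- pts[n + 1L, ]
  out
}

#' Generate a planar Koch suture curve
#'
#' Applies the classic triadic Koch generator (each segment replaced by four
#' segments of one-third length with an equilateral bump) `iterations` times
#' to each of `n_copies` baseline segments spanning the arc position
#' `[0, 1]`.  The resulting frill models the higher-order folding of
#' ammonitic suture lines; each copy becomes one primary lobe.
#'
#' @param iterations number of generator applications (0--6).
#' @param n_copies number of duplicated copies around the circumference
#'   (one primary lobe each); the reference suite uses 4.
#' @param amplitude peak-to-peak axial extent of the curve, mm.
#' @param smooth if `TRUE`, replace the polyline by a periodic cubic spline
#'   through the generator vertices (sampled at `points_per_segment` points
#'   per segment); the generator topology is retained.
#' @param points_per_segment sampling density used when `smooth = TRUE`.
#' @return a `planar_curve`; attribute `meta$n_segments` holds the
#'   unsmoothed segment count `n_copies * 4^iterations`.
#' @export
koch_curve <- function(iterations, n_copies = 4L, amplitude = 1,
                       smooth = TRUE, points_per_segment = 2L) {
  if (iterations < 0 || iterations > 6) {
    stop("`iterations` must be between 0 and 6", call. = FALSE)
  }
  if (n_copies < 1) stop("`n_copies` must be >= 1", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  iterations <- as.integer(iterations)
  pts <- cbind(x = seq(0, 1, length.out = n_copies + 1L), y = 0)
  for (i in seq_len(iterations)) pts <- koch_iterate_once(pts)
  n_seg <- n_copies * 4L^iterations
  # smooth in the generator's natural aspect ratio, then scale the
  # amplitude (a spline through the already-squashed curve oscillates)
  if (smooth && iterations > 0L) {
    pts <- periodic_resample(pts, n_out = points_per_segment * n_seg)
  }
  if (iterations > 0L) {
    yr <- range(pts[, 2])
    pts[, 2] <- (pts[, 2] - mean(yr)) / diff(yr) * amplitude
  }
  new_planar_curve(pts[-nrow(pts), , drop = FALSE], periodic = TRUE,
                   meta = list(family = "koch", iterations = iterations,
                               n_copies = n_copies, amplitude = amplitude,
                               n_segments = n_seg))
}

# parametric periodic cubic spline through an open polyline whose endpoints
# join across the period (x wraps by +1); returns n_out + 1 points
periodic_resample <- function(pts, n_out) {
  n <- nrow(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  t <- c(0, cumsum(seg)) / sum(seg)
  # remove the linear drift in x so both coordinates are periodic in t
  drift <- pts[n, 1] - pts[1, 1]
  xp <- pts[, 1] - drift * t
  yp <- pts[, 2]
  xp[n] <- xp[1]
  yp[n] <- yp[1]
  fx <- splinefun(t, xp, method = "periodic")
  fy <- splinefun(t, yp, method = "periodic")
  tt <- seq(0, 1, length.out = n_out + 1L)
  cbind(x = fx(tt) + drift * tt, y = fy(tt))
}

#' Generate a planar lobate suture curve
#'
#' Smooth periodic curve with exactly `n_lobes` primary lobes (local minima,
#' pointing apicalward) and `n_lobes` saddles per period, bilaterally
#' symmetric about every lobe axis.  The profile is a short cosine series in
#' the arc position; the default weights sharpen the lobes and broaden the
#' saddles, the shape seen in simple goniatitic suture lines.
#'
#' @param n_lobes number of primary lobes (the reference suite uses 3--6).
#' @param amplitude peak-to-peak axial extent, mm.
#' @param weights harmonic profile weights (multiples of the lobe frequency).
#' @param n_points number of polyline vertices per period.
#' @return a `planar_curve` with `meta$n_lobes`.
#' @export
lobate_curve <- function(n_lobes, amplitude, weights = c(1, 0.25, 0.05),
                         n_points = 120L * n_lobes) {
  if (n_lobes < 1) stop("`n_lobes` must be >= 1", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  x <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  u <- 2 * pi * n_lobes * x
  g <- rep(0, length(u))
  for (k in seq_along(weights)) g <- g + weights[k] * cos(k * u)
  gr <- range(g)
  y <- -(g - mean(gr)) / diff(gr) * amplitude
  new_planar_curve(cbind(x = x, y = y), periodic = TRUE,
                   meta = list(family = "lobate", n_lobes = n_lobes,
                               amplitude = amplitude, weights = weights))
}

# ---------------------------------------------------------------------------
# Wrapping onto the shell tube
# ---------------------------------------------------------------------------

new_suture_curve <- function(points, radius, axial_center, planar) {
  structure(list(points = points, radius = radius,
                 axial_center = axial_center, closed = TRUE,
                 planar = planar),
            class = "suture_curve")
}

#' @export
print.suture_curve <- function(x, ...) {
  cat(sprintf("<suture_curve: %d vertices on cylinder r = %.3f mm, z centre %.3f mm>\n",
              nrow(x$points), x$radius, x$axial_center))
  invisible(x)
}

#' Wrap a planar suture curve around a cylinder
#'
#' Maps arc position `x` to angle `theta = 2*pi*x` (counter-clockwise from
#' +x; cylinder axis = z) and axial amplitude `y` to `axial_center + y`,
#' producing the closed three-dimensional suture line where the septum meets
#' the shell wall.
#'
#' @param curve a `planar_curve` (periodic, or with joinable endpoints).
#' @param radius cylinder radius, mm.
#' @param axial_center axial position of the curve's midline, mm.
#' @param join_tol endpoint join tolerance for non-periodic input.
#' @return a `suture_curve`: closed polyline (first vertex repeated last),
#'   every vertex at distance `radius` from the z axis.
#' @export
wrap_on_cylinder <- function(curve, radius, axial_center = 0,
                             join_tol = 1e-8) {
  stopifnot(inherits(curve, "planar_curve"))
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  pts <- curve$points
  if (!curve$periodic) {
    gap <- abs(pts[nrow(pts), 1] - pts[1, 1] - round(pts[nrow(pts), 1] - pts[1, 1])) +
      abs(pts[nrow(pts), 2] - pts[1, 2])
    if (gap > join_tol) {
      stop("curve endpoints do not join on the cylinder (gap ",
           format(gap), ")", call. = FALSE)
    }
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  theta <- 2 * pi * pts[, 1]
  xyz <- cbind(x = radius * cos(theta), y = radius * sin(theta),
               z = axial_center + pts[, 2])
  xyz <- rbind(xyz, xyz[1, ])
  new_suture_curve(xyz, radius, axial_center, planar = curve)
}

# unrolled (s, z) representation of a closed suture curve, s = theta * r;
# open storage (closing vertex dropped), period 2*pi*r in s
unroll_suture <- function(suture) {
  pts <- suture$points
  pts <- pts[-nrow(pts), , drop = FALSE]
  if (!is.null(suture$planar)) {
    s <- suture$planar$points[, "x"] * 2 * pi * suture$radius
  } else {
    th <- atan2(pts[, 2], pts[, 1])
    th <- th %% (2 * pi)
    # unwrap assuming monotone-ish traversal
    th <- th + 2 * pi * cumsum(c(0, diff(th) < -pi))
    s <- th * suture$radius
  }
  cbind(s = s, z = pts[, 3])
}

#' Total arc length of a suture curve
#' @param suture a `suture_curve`.
#' @export
suture_arc_length <- function(suture) {
  sum(sqrt(rowSums(diff(suture$points)^2)))
}

# ---------------------------------------------------------------------------
# Offset safety: the largest half-thickness before the offset curves
# self-intersect (the constraint that forces thin Koch septa)
# ---------------------------------------------------------------------------

# brute-force simplicity check of a curve that closes around a cylinder:
# pts are unrolled (s, z) vertices (open storage); the closure edge runs to
# the first vertex shifted by +period in s (the seam), and the chain is
# additionally checked against its own periodic translate
polyline_is_simple <- function(pts, period) {
  n <- nrow(pts)
  a <- pts
  b <- rbind(pts[-1L, , drop = FALSE],
             pts[1L, , drop = FALSE] + c(period, 0))
  if (segment_pairs_intersect(a[, 1], a[, 2], b[, 1], b[, 2])) return(FALSE)
  if (segment_images_intersect(a[, 1], a[, 2], b[, 1], b[, 2], period)) {
    return(FALSE)
  }
  TRUE
}

# any proper intersection among non-consecutive segments of an open chain
segment_pairs_intersect <- function(ax, ay, bx, by) {
  n <- length(ax)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  adj <- (j - i == 1L)
  i <- i[!adj]; j <- j[!adj]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  d3 <- cross2(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d4 <- cross2(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

# intersections between the chain and its copy translated by +period in s
# (checking one translate suffices: the -period case is the same pair set)
segment_images_intersect <- function(ax, ay, bx, by, period) {
  reach <- pmax(ax, bx); base <- pmin(ax, bx)
  # pair (i, j-image) can intersect only if s-intervals overlap
  right <- which(reach >= min(base) + period)
  left <- which(base + period <= max(reach))
  if (!length(right) || !length(left)) return(FALSE)
  i <- rep(right, each = length(left))
  j <- rep(left, times = length(right))
  ok <- (i != j) & (reach[i] >= base[j] + period) & (base[i] <= reach[j] + period)
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(FALSE)
  sx <- ax[j] + period; sy <- ay[j]
  tx <- bx[j] + period; ty <- by[j]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross2(ax[i], ay[i], bx[i], by[i], sx, sy)
  d2 <- cross2(ax[i], ay[i], bx[i], by[i], tx, ty)
  d3 <- cross2(sx, sy, tx, ty, ax[i], ay[i])
  d4 <- cross2(sx, sy, tx, ty, bx[i], by[i])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

# offset a closed polyline (open storage) by signed distance d along miter
# vertex normals; normals point toward +z for d > 0
offset_polyline <- function(pts, d, period) {
  n <- nrow(pts)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  t1 <- pts - pts[prv, , drop = FALSE]
  t2 <- pts[nxt, , drop = FALSE] - pts
  # wrap neighbours live one period away in s
  t1[1L, 1] <- t1[1L, 1] + period
  t2[n, 1] <- t2[n, 1] + period
  norm1 <- sqrt(rowSums(t1^2)); norm2 <- sqrt(rowSums(t2^2))
  # left normals of incoming/outgoing segments
  n1 <- cbind(-t1[, 2], t1[, 1]) / norm1
  n2 <- cbind(-t2[, 2], t2[, 1]) / norm2
  m <- n1 + n2
  mlen2 <- rowSums(m^2)
  # miter scale 2/|n1+n2|^2 gives exact parallel offset; clamp sharp spikes
  scale <- pmin(2 / pmax(mlen2, 1e-12), 4)
  pts + d * m * scale
}

#' Largest safe offset half-thickness of a suture curve
#'
#' Finds, by bisection over a brute-force segment-intersection check on the
#' unrolled cylinder plane, the largest normal-offset half-thickness for
#' which both offset curves (toward +z and -z) remain simple.  Thickening a
#' septum beyond twice this value makes the suture-line frills collide --
#' the constraint that limits Koch-model septal thickness.
#'
#' @param suture a `suture_curve` (simple and closed).
#' @param upper upper search bound, mm (default: cylinder radius).
#' @param tol bisection tolerance, mm.
#' @return safe half-thickness in mm (`upper` if no collision is found).
#' @export
max_safe_offset <- function(suture, upper = suture$radius, tol = 1e-3) {
  stopifnot(inherits(suture, "suture_curve"))
  period <- 2 * pi * suture$radius
  pts <- unroll_suture(suture)
  if (!polyline_is_simple(pts, period)) {
    stop("suture curve is not simple (self-intersects)", call. = FALSE)
  }
  offsets_simple <- function(d) {
    polyline_is_simple(offset_polyline(pts, d, period), period) &&
      polyline_is_simple(offset_polyline(pts, -d, period), period)
  }
  if (offsets_simple(upper)) return(upper)
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (offsets_simple(mid)) lo <- mid else hi <- mid
  }
  lo
}

# ---------------------------------------------------------------------------
# Polyline CSV interchange
# ---------------------------------------------------------------------------

#' Write a suture curve as a CSV polyline
#'
#' One row per vertex (columns x, y, z in mm); a comment header records the
#' closed flag and cylinder radius.
#' @param suture a `suture_curve`.
#' @param path output file.
#' @export
write_suture_csv <- function(suture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# closed=%s radius=%.9g axial_center=%.9g",
                     suture$closed, suture$radius, suture$axial_center), con)
  writeLines("x,y,z", con)
  pts <- suture$points[-nrow(suture$points), , drop = FALSE]
  writeLines(sprintf("%.9g,%.9g,%.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  invisible(path)
}

#' Read a suture curve written by [write_suture_csv()]
#' @param path CSV file.
#' @export
read_suture_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  radius <- as.numeric(sub(".*radius=([-0-9.eE+]+).*", "\\1", hdr))
  centre <- as.numeric(sub(".*axial_center=([-0-9.eE+]+).*", "\\1", hdr))
  pts <- as.matrix(read.csv(path, comment.char = "#"))
  pts <- rbind(pts, pts[1, ])
  colnames(pts) <- c("x", "y", "z")
  new_suture_curve(pts, radius, centre, planar = NULL)
}

#' Count local minima of a periodic sampled curve
#'
#' Sign-change count of the discrete derivative from negative to positive,
#' used to verify the lobe count of generated suture profiles.
#' @param curve a `planar_curve`.
#' @export
count_local_minima <- function(curve) {
  y <- curve$points[, "y"]
  d <- diff(c(y, y[1]))
  s <- sign(d)
  s <- s[s != 0]
  sum(s == 1 & c(s[length(s)], s[-length(s)]) == -1)
}
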