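# ---------------------------------------------------------------------------
# Shell assembly: capped double-walled cylinder with N septa, meshed into
# conforming tetrahedra.  The construction is conformal by design: septal
# boundary rings are generated as node rings of the inner wall surface, so
# septum/wall fusion is exact and needs no boolean union or mesh repair.
# ---------------------------------------------------------------------------

#' Material constants for the shell
#'
#' Defaults: isotropic elastic modulus 70 GPa (stored as 70000 MPa, the
#' nacre/spherulitic-prismatic value from nanoindentation of *Nautilus*
#' shell) and Poisson's ratio 0.3.
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @export
material_params <- function(E = 70000, nu = 0.3) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  list(E = E, nu = nu)
}

#' Suture-line specification
#'
#' @param family `"lobate"` or `"koch"`.
#' @param n_lobes primary lobe count (lobate family).
#' @param iterations Koch generator iterations.
#' @param n_copies Koch duplication count (primary lobes).
#' @param amplitude peak-to-peak axial extent, mm; `NULL` means the model
#'   default of 0.2 x inner radius.
#' @export
suture_spec <- function(family = c("lobate", "koch"), n_lobes = 4L,
                        iterations = 1L, n_copies = 4L, amplitude = NULL) {
  family <- match.arg(family)
  structure(list(family = family, n_lobes = as.integer(n_lobes),
                 iterations = as.integer(iterations),
                 n_copies = as.integer(n_copies), amplitude = amplitude),
            class = "suture_spec")
}

#' Model configuration for one phragmocone shell
#'
#' Geometry defaults follow the reference model suite: inner radius
#' 9.11 mm; wall thickness 0.5 mm (outer radius 9.61 mm) or 0.1 mm
#' (9.21 mm); septal spacings 5/10/20 mm carrying 5/3/2 septa so the span
#' between outermost septa is always 20 mm; septal thickness 0.4 mm
#' (lobate) or 0.04 mm (Koch); hemispherical end caps beyond an end margin.
#'
#' @param inner_radius inner cylinder radius, mm.
#' @param shell_thickness wall thickness, mm.
#' @param septal_spacing axial distance between septa, mm.
#' @param n_septa number of septa; default `floor(20/spacing) + 1`.
#' @param suture a [suture_spec()].
#' @param septal_thickness septum thickness, mm (default by family).
#' @param end_margin cylinder length beyond the outermost septa, mm.
#' @param pressure external hydrostatic pressure, MPa.
#' @param material a [material_params()].
#' @export
model_config <- function(inner_radius = 9.11, shell_thickness = 0.5,
                         septal_spacing = 5, n_septa = NULL,
                         suture = suture_spec("lobate", n_lobes = 6L),
                         septal_thickness = NULL, end_margin = 20,
                         pressure = 2, material = material_params()) {
  if (is.null(n_septa)) n_septa <- as.integer(floor(20 / septal_spacing)) + 1L
  n_septa <- as.integer(n_septa)
  if (is.null(septal_thickness)) {
    septal_thickness <- if (suture$family == "koch") 0.04 else 0.4
  }
  if (is.null(suture$amplitude)) suture$amplitude <- 0.2 * inner_radius
  if (n_septa > 0 && septal_spacing <= septal_thickness) {
    stop("septal spacing must exceed septal thickness", call. = FALSE)
  }
  cfg <- structure(list(inner_radius = inner_radius,
                        shell_thickness = shell_thickness,
                        outer_radius = inner_radius + shell_thickness,
                        septal_spacing = septal_spacing, n_septa = n_septa,
                        suture = suture, septal_thickness = septal_thickness,
                        end_margin = end_margin, pressure = pressure,
                        material = material),
                   class = "model_config")
  cfg$length <- max(0, n_septa - 1L) * septal_spacing + 2 * end_margin
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  su <- x$suture
  sdesc <- if (su$family == "koch") {
    sprintf("koch iter %d x%d", su$iterations, su$n_copies)
  } else sprintf("%d-lobate", su$n_lobes)
  cat(sprintf("<model_config: r_i %.2f, wall %.2f mm, %d septa @ %.0f mm (%s, %.2g mm), L %.0f mm, P %.1f MPa>\n",
              x$inner_radius, x$shell_thickness, x$n_septa, x$septal_spacing,
              sdesc, x$septal_thickness, x$length, x$pressure))
  invisible(x)
}

#' Mesh resolution options
#'
#' @param n_theta circumferential node count (multiple of 4); default from
#'   `target_size`.
#' @param target_size requested element size, mm.
#' @param order element order: 1 (linear) or 2 (quadratic, the default).
#' @param n_radial element layers through the wall thickness.
#' @param septum_rings radial rings of the septal disc mesh.
#' @param cap_rings meridional rings of each hemispherical cap.
#' @export
mesh_options <- function(n_theta = NULL, target_size = 1.2, order = 2L,
                         n_radial = 1L, septum_rings = NULL,
                         cap_rings = NULL) {
  structure(list(n_theta = n_theta, target_size = target_size,
                 order = as.integer(order), n_radial = as.integer(n_radial),
                 septum_rings = septum_rings, cap_rings = cap_rings),
            class = "mesh_options")
}

# geometrically graded breakpoints across an interval of length `total`:
# row heights start at `first_a` / `first_b` at the two ends and grow by
# `ratio` up to `target`; the middle is filled uniformly.  Returns interior
# positions in (0, total).
graded_breaks <- function(total, first_a, first_b = first_a, ratio = 1.8,
                          target = Inf) {
  ladder <- function(first, lim) {
    g <- c(); x <- 0
    gap <- first
    while (x + gap < lim) {
      g <- c(g, gap)
      x <- x + gap
      gap <- min(gap * ratio, target)
    }
    g
  }
  la <- ladder(first_a, total / 2)
  lb <- ladder(first_b, total / 2)
  middle <- total - sum(la) - sum(lb)
  n_mid <- max(1L, ceiling(middle / min(target, total)))
  pos <- c(cumsum(la),
           sum(la) + middle * seq_len(n_mid - 1L) / n_mid,
           total - rev(cumsum(lb)))
  sort(unique(pos[pos > 1e-9 & pos < total - 1e-9]))
}

# planar suture curve for a config
config_suture_curve <- function(config) {
  su <- config$suture
  if (su$family == "koch") {
    koch_curve(su$iterations, su$n_copies, su$amplitude, smooth = TRUE)
  } else {
    lobate_curve(su$n_lobes, su$amplitude)
  }
}

# single-valued axial height profile y(theta grid) of a planar curve.
# Koch curves of iteration >= 2 have small overhangs; these are collapsed
# by a monotone (cummax) projection of the arc position.
height_profile <- function(curve, n_theta) {
  pts <- curve$points
  x <- pts[, 1]; y <- pts[, 2]
  x <- c(x, x[1] + 1); y <- c(y, y[1])
  xm <- cummax(x)
  grid <- seq(0, 1, length.out = n_theta + 1L)[seq_len(n_theta)]
  approx(xm, y, xout = grid, rule = 2, ties = mean)$y
}

resolve_mesh <- function(config, mesh) {
  r <- config$inner_radius
  if (is.null(mesh$n_theta)) {
    n <- ceiling(2 * pi * r / mesh$target_size / 4) * 4
    mesh$n_theta <- max(48L, as.integer(n))
  }
  if (mesh$n_theta %% 4L != 0L) {
    mesh$n_theta <- as.integer(ceiling(mesh$n_theta / 4) * 4)
  }
  if (is.null(mesh$cap_rings)) {
    mesh$cap_rings <- max(4L, as.integer(ceiling(pi * r / 2 / mesh$target_size)))
  }
  if (is.null(mesh$septum_rings)) {
    mesh$septum_rings <- max(6L, as.integer(ceiling(r / mesh$target_size)))
  }
  mesh
}

#' Assemble the solid phragmocone model
#'
#' Builds the annular shell wall, two hemispherical caps and `n_septa`
#' thickened minimum-curvature septa fused to the inner wall, as one
#' conforming prismatic solid with region labels.  Septal boundary rings
#' are node rings of the wall surface grid, so the assembly is watertight
#' and conformal by construction.
#'
#' @param config a [model_config()].
#' @param mesh a [mesh_options()].
#' @return a `solid_mesh`: global nodes, per-node metadata, labelled prism
#'   blocks, boundary `shell` triangulation and external-surface facets.
#' @export
build_shell <- function(config, mesh = mesh_options()) {
  stopifnot(inherits(config, "model_config"))
  mesh <- resolve_mesh(config, mesh)
  nt <- mesh$n_theta
  nr <- mesh$n_radial
  ri <- config$inner_radius
  t_w <- config$shell_thickness
  L <- config$length
  N <- config$n_septa
  ts <- config$septal_thickness
  theta <- 2 * pi * (seq_len(nt) - 1L) / nt

  # axial height profile of the suture at the wall theta grid
  if (N > 0) {
    pc <- config_suture_curve(config)
    prof <- height_profile(pc, nt)
    z_sep <- (seq_len(N) - (N + 1) / 2) * config$septal_spacing
  } else {
    pc <- NULL; prof <- numeric(0); z_sep <- numeric(0)
  }

  # --- axial levels per theta column -------------------------------------
  # base levels: bottom cap joint, per-septum bottom/top rings, top joint
  n_base <- 2L + 2L * N
  base <- matrix(0, n_base, nt)
  base[1, ] <- -L / 2
  base[n_base, ] <- L / 2
  if (N > 0) {
    for (s in seq_len(N)) {
      base[2L * s, ] <- z_sep[s] - ts / 2 + prof
      base[2L * s + 1L, ] <- z_sep[s] + ts / 2 + prof
    }
  }
  if (any(diff(base) <= 0)) {
    stop("septa overlap the caps or each other; increase spacing or margin",
         call. = FALSE)
  }
  # subdivision per base interval: septum strips stay one element; other
  # intervals are graded so rows refine toward the suture rings, where the
  # septal frills load the wall
  arc <- 2 * pi * ri / nt
  refine0 <- min(mesh$target_size / 2, 1.2 * arc)
  n_int <- n_base - 1L
  fracs <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    is_strip <- N > 0 && i %% 2L == 0L
    len <- max(base[i + 1L, ] - base[i, ])
    if (is_strip) {
      fracs[[i]] <- 1
    } else {
      # end refinement: fine at septum rings, moderate at cap joints
      cap_gap <- min(1, mesh$target_size)
      g_lo <- if (i == 1L) cap_gap else refine0
      g_hi <- if (i == n_int) cap_gap else refine0
      br <- graded_breaks(len, first_a = g_lo, first_b = g_hi,
                          ratio = 2.4, target = mesh$target_size)
      fracs[[i]] <- c(br / len, 1)
    }
  }
  nsub <- vapply(fracs, length, 1L)
  nz <- 1L + sum(nsub)
  Z <- matrix(0, nz, nt)
  lvl <- 1L
  row_of_base <- integer(n_base)
  row_of_base[1] <- 1L
  Z[1, ] <- base[1, ]
  for (i in seq_len(n_int)) {
    for (w in fracs[[i]]) {
      lvl <- lvl + 1L
      Z[lvl, ] <- (1 - w) * base[i, ] + w * base[i + 1L, ]
    }
    row_of_base[i + 1L] <- lvl
  }
  ring_bot <- if (N > 0) row_of_base[2L * seq_len(N)] else integer(0)
  ring_top <- if (N > 0) row_of_base[2L * seq_len(N) + 1L] else integer(0)

  # --- wall nodes --------------------------------------------------------
  # id(i, j, k) for radial layer i = 0..nr, theta j, level k
  wall_id <- function(i, j, k) ((k - 1L) * nt + (j - 1L)) * (nr + 1L) + i + 1L
  n_wall <- (nr + 1L) * nt * nz
  radii <- ri + t_w * (0:nr) / nr
  jj <- rep(rep(seq_len(nt), each = nr + 1L), times = nz)
  kk <- rep(seq_len(nz), each = (nr + 1L) * nt)
  ii <- rep(0:nr, times = nt * nz)
  zz <- Z[cbind(kk, jj)]
  nodes <- cbind(radii[ii + 1L] * cos(theta[jj]),
                 radii[ii + 1L] * sin(theta[jj]), zz)
  meta <- data.frame(comp = rep("wall", n_wall), layer = ii, itheta = jj,
                     klevel = kk, ring = NA_integer_,
                     stringsAsFactors = FALSE)

  node_blocks <- list(nodes)
  meta_blocks <- list(meta)
  next_id <- n_wall

  # --- caps --------------------------------------------------------------
  dm_cap <- disc_mesh(nt, mesh$cap_rings)
  nv_cap <- nrow(dm_cap$param)
  cap_rho <- sqrt(rowSums(dm_cap$param^2))
  cap_ang <- atan2(dm_cap$param[, 2], dm_cap$param[, 1])
  cap_maps <- list()   # [[side]][[layer i+1]] = global ids for disc verts
  for (side in c("bottom", "top")) {
    zc <- if (side == "bottom") -L / 2 else L / 2
    sgn <- if (side == "bottom") -1 else 1
    interior <- setdiff(seq_len(nv_cap), dm_cap$boundary)
    phi <- cap_rho * pi / 2  # 0 at pole, pi/2 at equator
    dirx <- sin(phi) * cos(cap_ang)
    diry <- sin(phi) * sin(cap_ang)
    dirz <- sgn * cos(phi)
    maps <- vector("list", nr + 1L)
    for (i in 0:nr) {
      ids <- integer(nv_cap)
      kend <- if (side == "bottom") 1L else nz
      ids[dm_cap$boundary] <- wall_id(i, seq_len(nt), kend)
      newpts <- cbind(radii[i + 1L] * dirx[interior],
                      radii[i + 1L] * diry[interior],
                      zc + radii[i + 1L] * dirz[interior])
      ids[interior] <- next_id + seq_len(length(interior))
      next_id <- next_id + length(interior)
      node_blocks[[length(node_blocks) + 1L]] <- newpts
      meta_blocks[[length(meta_blocks) + 1L]] <-
        data.frame(comp = paste0("cap_", side), layer = i,
                   itheta = NA_integer_, klevel = NA_integer_,
                   ring = dm_cap$ring[interior], stringsAsFactors = FALSE)
      maps[[i + 1L]] <- ids
    }
    cap_maps[[side]] <- maps
  }

  # --- septa -------------------------------------------------------------
  # one midsurface solve (all septa share the suture shape), translated
  sep_maps <- list()
  dm_sep <- NULL; sep_surface <- NULL
  if (N > 0) {
    suture0 <- wrap_on_cylinder(
      new_planar_curve(cbind(x = (seq_len(nt) - 1) / nt, y = prof),
                       periodic = TRUE),
      radius = ri, axial_center = 0)
    sep_surface <- min_curvature_surface(
      suture0, target_edge_length = 2 * pi * ri / nt * 1.3,
      tol = 1e-8, max_iter = 40L, n_rings = mesh$septum_rings)
    # force the ring count expected by the wall grid
    dm_sep <- sep_surface$param
    nv_sep <- nrow(sep_surface$vertices)
    nrm <- vertex_normals(sep_surface$vertices, sep_surface$triangles)
    # orient normals toward +z (apical)
    if (mean(nrm[, 3]) < 0) nrm <- -nrm
    interior <- setdiff(seq_len(nv_sep), sep_surface$boundary)
    for (s in seq_len(N)) {
      maps <- vector("list", 2L)
      for (l in 0:1) {
        ids <- integer(nv_sep)
        kring <- if (l == 0L) ring_bot[s] else ring_top[s]
        ids[sep_surface$boundary] <- wall_id(0L, seq_len(nt), kring)
        off <- (l - 0.5) * ts
        newpts <- cbind(sep_surface$vertices[interior, 1] + off * nrm[interior, 1],
                        sep_surface$vertices[interior, 2] + off * nrm[interior, 2],
                        sep_surface$vertices[interior, 3] + off * nrm[interior, 3] +
                          z_sep[s])
        ids[interior] <- next_id + seq_len(length(interior))
        next_id <- next_id + length(interior)
        node_blocks[[length(node_blocks) + 1L]] <- newpts
        meta_blocks[[length(meta_blocks) + 1L]] <-
          data.frame(comp = sprintf("septum_%d", s), layer = l,
                     itheta = NA_integer_, klevel = NA_integer_,
                     ring = dm_sep$ring[interior], stringsAsFactors = FALSE)
        maps[[l + 1L]] <- ids
      }
      sep_maps[[s]] <- maps
    }
  }

  nodes <- do.call(rbind, node_blocks)
  colnames(nodes) <- c("x", "y", "z")
  meta <- do.call(rbind, meta_blocks)
  meta$z <- nodes[, 3]

  # --- wall surface grid triangles ---------------------------------------
  jn <- c(2:nt, 1L)
  qj <- rep(seq_len(nt), times = nz - 1L)
  qk <- rep(seq_len(nz - 1L), each = nt)
  # quad corners (j,k), (j+1,k), (j+1,k+1), (j,k+1) as vertex grid refs;
  # triangles (j,k)(j+1,k)(j+1,k+1) and (j,k)(j+1,k+1)(j,k+1)
  wall_tris_grid <- rbind(cbind(qj, jn[qj], jn[qj], qk, qk, qk + 1L),
                          cbind(qj, jn[qj], qj, qk, qk + 1L, qk + 1L))
  # columns: j1 j2 j3 k1 k2 k3 (triangle vertices in (j,k) grid)
  wall_tri_strip <- rep(qk %in% (ring_bot), 2L)  # row k = strip below ring_top

  wall_tri_ids <- function(i) {
    cbind(wall_id(i, wall_tris_grid[, 1], wall_tris_grid[, 4]),
          wall_id(i, wall_tris_grid[, 2], wall_tris_grid[, 5]),
          wall_id(i, wall_tris_grid[, 3], wall_tris_grid[, 6]))
  }

  # --- prisms with region labels -----------------------------------------
  prism_blocks <- list(); prism_regions <- character(0)
  add_prisms <- function(bot, top, region) {
    prism_blocks[[length(prism_blocks) + 1L]] <<- cbind(bot, top)
    prism_regions <<- c(prism_regions, region)
  }
  for (i in seq_len(nr)) {
    add_prisms(wall_tri_ids(i - 1L), wall_tri_ids(i), "shell_wall")
  }
  for (side in c("bottom", "top")) {
    Fc <- dm_cap$triangles
    for (i in seq_len(nr)) {
      m0 <- cap_maps[[side]][[i]]
      m1 <- cap_maps[[side]][[i + 1L]]
      add_prisms(cbind(m0[Fc[, 1]], m0[Fc[, 2]], m0[Fc[, 3]]),
                 cbind(m1[Fc[, 1]], m1[Fc[, 2]], m1[Fc[, 3]]),
                 paste0("cap_", side))
    }
  }
  if (N > 0) {
    Fs <- sep_surface$triangles
    for (s in seq_len(N)) {
      m0 <- sep_maps[[s]][[1]]
      m1 <- sep_maps[[s]][[2]]
      add_prisms(cbind(m0[Fs[, 1]], m0[Fs[, 2]], m0[Fs[, 3]]),
                 cbind(m1[Fs[, 1]], m1[Fs[, 2]], m1[Fs[, 3]]),
                 sprintf("septum_%d", s))
    }
  }

  # --- external surface (pressure) facets --------------------------------
  ext_wall <- wall_tri_ids(nr)
  mo <- cap_maps[["bottom"]][[nr + 1L]]
  Fc <- dm_cap$triangles
  ext_capb <- cbind(mo[Fc[, 1]], mo[Fc[, 2]], mo[Fc[, 3]])
  mo <- cap_maps[["top"]][[nr + 1L]]
  ext_capt <- cbind(mo[Fc[, 1]], mo[Fc[, 2]], mo[Fc[, 3]])
  external <- rbind(ext_wall, ext_capb, ext_capt)
  # orient outward (the external surface is convex about the origin)
  fn <- tri_face_normals(nodes, external, normalize = FALSE)
  cen <- (nodes[external[, 1], ] + nodes[external[, 2], ] +
            nodes[external[, 3], ]) / 3
  ref <- cen
  ref[, 3] <- pmax(pmin(ref[, 3], L / 2), -L / 2) * 0 +
    pmin(pmax(cen[, 3], -L / 2), L / 2)
  flip <- rowSums(fn * (cen - cbind(0, 0, ref[, 3]))) < 0
  external[flip, ] <- external[flip, c(1, 3, 2)]

  # --- boundary shell with labels (for export / watertight checks) -------
  shell_tris <- list(); shell_lab <- character(0)
  add_shell <- function(tris, lab) {
    shell_tris[[length(shell_tris) + 1L]] <<- tris
    shell_lab <<- c(shell_lab, lab)
  }
  # use the outward-reoriented copies for the boundary shell
  n_ew <- nrow(ext_wall); n_eb <- nrow(ext_capb)
  add_shell(external[seq_len(n_ew), , drop = FALSE], "shell_wall")
  add_shell(external[n_ew + seq_len(n_eb), , drop = FALSE], "cap_bottom")
  add_shell(external[(n_ew + n_eb + 1):nrow(external), , drop = FALSE],
            "cap_top")
  inner_wall <- wall_tri_ids(0L)[, c(1, 3, 2)]
  keep <- !wall_tri_strip
  add_shell(inner_wall[keep, , drop = FALSE], "shell_wall_inner")
  # the bottom cap disc is z-mirrored, so its raw orientation already
  # points into the cavity; only the top inner cap needs flipping
  mi <- cap_maps[["bottom"]][[1]]
  add_shell(cbind(mi[Fc[, 1]], mi[Fc[, 2]], mi[Fc[, 3]]), "cap_bottom_inner")
  mi <- cap_maps[["top"]][[1]]
  add_shell(cbind(mi[Fc[, 1]], mi[Fc[, 3]], mi[Fc[, 2]]), "cap_top_inner")
  if (N > 0) {
    Fs <- sep_surface$triangles
    for (s in seq_len(N)) {
      m0 <- sep_maps[[s]][[1]]; m1 <- sep_maps[[s]][[2]]
      add_shell(cbind(m0[Fs[, 1]], m0[Fs[, 3]], m0[Fs[, 2]]),
                sprintf("septum_%d_bottom", s))
      add_shell(cbind(m1[Fs[, 1]], m1[Fs[, 2]], m1[Fs[, 3]]),
                sprintf("septum_%d_top", s))
    }
  }
  shell <- list(vertices = nodes,
                triangles = do.call(rbind, shell_tris),
                labels = rep(shell_lab, vapply(shell_tris, nrow, 1L)))

  prisms <- do.call(rbind, prism_blocks)
  storage.mode(prisms) <- "integer"
  storage.mode(external) <- "integer"
  structure(list(config = config, mesh = mesh, nodes = nodes,
                 node_meta = meta,
                 prisms = prisms,
                 prism_region = rep(prism_regions,
                                    vapply(prism_blocks, nrow, 1L)),
                 external = external, shell = shell,
                 z_levels = Z, ring_bot = ring_bot, ring_top = ring_top,
                 z_septa = z_sep, septum_surface = sep_surface,
                 profile = if (N > 0) prof else NULL,
                 theta = theta, n_theta = nt, nz = nz),
            class = "solid_mesh")
}

#' @export
print.solid_mesh <- function(x, ...) {
  cat(sprintf("<solid_mesh: %d nodes, %d prisms (%s)>\n", nrow(x$nodes),
              nrow(x$prisms), paste(unique(x$prism_region), collapse = ", ")))
  invisible(x)
}

# split prisms (m x 6 global ids, bottom 1:3 / top 4:6 with i+3 above i)
# into 3 tets each using the min-index diagonal rule, which guarantees
# conforming faces between neighbouring prisms
split_prisms <- function(P) {
  m <- nrow(P)
  perms <- rbind(c(1, 2, 3, 4, 5, 6),
                 c(2, 3, 1, 5, 6, 4),
                 c(3, 1, 2, 6, 4, 5),
                 c(4, 6, 5, 1, 3, 2),
                 c(5, 4, 6, 2, 1, 3),
                 c(6, 5, 4, 3, 2, 1))
  amin <- max.col(-P, ties.method = "first")
  Q <- matrix(0, m, 6)
  for (p in 1:6) {
    rows <- amin == p
    if (any(rows)) Q[rows, ] <- P[rows, perms[p, ], drop = FALSE]
  }
  caseA <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0, 3L * m, 4)
  idx <- seq_len(m)
  # case A: diagonal 2-6; case B: diagonal 3-5
  tets[3 * idx - 2L, ] <- cbind(Q[, 1], Q[, 2], Q[, 3],
                                ifelse(caseA, Q[, 6], Q[, 5]))
  tets[3 * idx - 1L, ] <- cbind(Q[, 1],
                                ifelse(caseA, Q[, 2], Q[, 5]),
                                ifelse(caseA, Q[, 6], Q[, 3]),
                                ifelse(caseA, Q[, 5], Q[, 6]))
  tets[3 * idx, ] <- cbind(Q[, 1], Q[, 5], Q[, 6], Q[, 4])
  storage.mode(tets) <- "integer"
  tets
}

#' Tetrahedralise an assembled solid
#'
#' Splits the labelled prism blocks into conforming tetrahedra (min-index
#' diagonal rule), orients all elements to positive volume and, for
#' `order = 2`, inserts midside nodes on every unique edge (10-node
#' quadratic tets).  External pressure facets are carried over (6-node
#' facets at order 2).
#'
#' @param solid a `solid_mesh` from [build_shell()].
#' @param order element order (1 or 2); defaults to the mesh options used
#'   at build time.
#' @return an `fe_mesh`: `nodes`, `tets`, `element_region`,
#'   `external` facets, `node_meta`, and a `quality` summary.
#' @export
tet_mesh <- function(solid, order = NULL) {
  stopifnot(inherits(solid, "solid_mesh"))
  if (is.null(order)) order <- solid$mesh$order
  tets <- split_prisms(solid$prisms)
  region <- rep(solid$prism_region, each = 3L)
  nodes <- solid$nodes
  vol <- as.numeric(tet_volumes(nodes, tets))
  neg <- vol < 0
  if (any(neg)) {
    tets[neg, ] <- tets[neg, c(2, 1, 3, 4)]
    vol <- abs(vol)
  }
  if (any(vol <= 0)) stop("degenerate tetrahedra in mesh", call. = FALSE)
  out <- structure(list(nodes = nodes, tets = tets, element_region = region,
                        external = solid$external,
                        node_meta = solid$node_meta, order = 1L,
                        n_corner = nrow(solid$nodes), edge_ends = NULL,
                        config = solid$config, solid = solid,
                        quality = list(n_elements = nrow(tets),
                                       n_nodes = nrow(nodes),
                                       min_volume = min(vol),
                                       max_volume = max(vol),
                                       total_volume = sum(vol),
                                       n_inverted = 0L)),
                   class = "fe_mesh")
  if (order == 2L) out <- promote_to_quadratic(out)
  out
}

#' Promote a linear tetrahedral mesh to quadratic (10-node) elements
#'
#' Inserts a midside node on every unique edge and upgrades external
#' pressure facets to 6-node triangles.
#' @param mesh an order-1 `fe_mesh`.
#' @export
promote_to_quadratic <- function(mesh) {
  stopifnot(mesh$order == 1L)
  nodes <- mesh$nodes
  tets <- mesh$tets
  np <- nrow(nodes)
  ep <- rbind(tets[, c(1, 2)], tets[, c(2, 3)], tets[, c(3, 1)],
              tets[, c(1, 4)], tets[, c(2, 4)], tets[, c(3, 4)])
  key <- pmin(ep[, 1], ep[, 2]) * (np + 1) + pmax(ep[, 1], ep[, 2])
  ukey <- unique(key)
  mid_id <- match(key, ukey) + np
  m <- nrow(tets)
  tets <- cbind(tets, matrix(mid_id, nrow = m, ncol = 6))
  storage.mode(tets) <- "integer"
  ua <- floor(ukey / (np + 1)); ub <- ukey - ua * (np + 1)
  midpts <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  nodes <- rbind(nodes, midpts)
  meta <- mesh$node_meta
  if (!is.null(meta)) {
    meta_mid <- data.frame(comp = NA_character_, layer = NA_integer_,
                           itheta = NA_integer_, klevel = NA_integer_,
                           ring = NA_integer_, z = midpts[, 3],
                           stringsAsFactors = FALSE)
    meta <- rbind(meta, meta_mid)
  }
  fkey <- function(a, b) pmin(a, b) * (np + 1) + pmax(a, b)
  external <- mesh$external
  external <- cbind(external,
                    match(fkey(external[, 1], external[, 2]), ukey) + np,
                    match(fkey(external[, 2], external[, 3]), ukey) + np,
                    match(fkey(external[, 3], external[, 1]), ukey) + np)
  if (anyNA(external)) {
    stop("external facets are not faces of the tetrahedral mesh", call. = FALSE)
  }
  storage.mode(external) <- "integer"
  mesh$nodes <- nodes
  mesh$tets <- tets
  mesh$external <- external
  mesh$node_meta <- meta
  mesh$order <- 2L
  mesh$edge_ends <- cbind(ua, ub)
  mesh$quality$n_nodes <- nrow(nodes)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh: %d nodes, %d tets (order %d), volume %.4g mm^3>\n",
              nrow(x$nodes), nrow(x$tets), x$order, x$quality$total_volume))
  invisible(x)
}

#' Analytic solid volume of a septa-free capped shell
#'
#' Annular wall plus two hemispherical shell caps; the reference for
#' mesh-volume conservation checks.
#' @param config a [model_config()] (septa ignored).
#' @export
analytic_shell_volume <- function(config) {
  ri <- config$inner_radius; ro <- config$outer_radius
  L <- config$length
  pi * (ro^2 - ri^2) * L + 4 / 3 * pi * (ro^3 - ri^3)
}
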