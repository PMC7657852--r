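# ---------------------------------------------------------------------------
# Triangle-surface utilities shared by the septum solver and shell assembly.
# Surfaces are lists: vertices (N x 3), triangles (M x 3, 1-based, CCW).
# ---------------------------------------------------------------------------

tri_corner_coords <- function(V, F) {
  list(p1 = V[F[, 1], , drop = FALSE],
       p2 = V[F[, 2], , drop = FALSE],
       p3 = V[F[, 3], , drop = FALSE])
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

tri_face_normals <- function(V, F, normalize = TRUE) {
  p <- tri_corner_coords(V, F)
  n <- cross3(p$p2 - p$p1, p$p3 - p$p1)
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    n <- n / pmax(len, 1e-300)
  }
  n
}

tri_areas <- function(V, F) {
  p <- tri_corner_coords(V, F)
  0.5 * sqrt(rowSums(cross3(p$p2 - p$p1, p$p3 - p$p1)^2))
}

# area-weighted vertex normals
vertex_normals <- function(V, F) {
  fn <- tri_face_normals(V, F, normalize = FALSE)  # magnitude = 2 * area
  n <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], F[, k])
      n[as.integer(rownames(acc)), c] <- n[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

# cotangent Laplacian (symmetric PSD, L = D - W) and barycentric vertex areas
cotan_laplacian <- function(V, F, clamp = 1e6) {
  i1 <- F[, 1]; i2 <- F[, 2]; i3 <- F[, 3]
  p <- tri_corner_coords(V, F)
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a
    u <- b - a; v <- c - a
    num <- rowSums(u * v)
    den <- sqrt(rowSums(cross3(u, v)^2))
    pmin(pmax(num / pmax(den, 1e-300), -clamp), clamp)
  }
  c1 <- cot_at(p$p1, p$p2, p$p3)  # opposite edge (2,3)
  c2 <- cot_at(p$p2, p$p3, p$p1)  # opposite edge (3,1)
  c3 <- cot_at(p$p3, p$p1, p$p2)  # opposite edge (1,2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- rep(c(c1, c2, c3), each = 1)
  ww <- c(c1, c1, c2, c2, c3, c3) / 2
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                            dims = c(nrow(V), nrow(V)))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  A <- tri_areas(V, F)
  vert_area <- rep(0, nrow(V))
  for (k in 1:3) {
    acc <- rowsum(A / 3, F[, k])
    vert_area[as.integer(rownames(acc))] <-
      vert_area[as.integer(rownames(acc))] + acc
  }
  list(L = L, area = vert_area)
}

# undirected edge table (each row sorted); attr count = multiplicity
mesh_edges <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  es <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  es
}

#' Check that a triangle surface is a closed 2-manifold
#'
#' Every undirected edge must be shared by exactly two triangles.
#' @param surface list with `vertices` and `triangles`, or a `tri_surface`.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(surface) {
  F <- surface$triangles
  es <- mesh_edges(F)
  key <- paste(es[, 1], es[, 2])
  all(table(key) == 2L)
}

# ordered boundary loop(s) of an open manifold surface; returns vertex index
# vector for the single loop (errors if not exactly one)
boundary_loop <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkeys <- names(tab)[tab == 1L]
  if (!length(bkeys)) stop("surface is closed; no boundary", call. = FALSE)
  be <- e[key %in% bkeys, , drop = FALSE]  # directed boundary edges
  nxt <- setNames(be[, 2], as.character(be[, 1]))
  if (length(nxt) != nrow(be)) stop("non-manifold boundary", call. = FALSE)
  start <- be[1, 1]
  loop <- integer(nrow(be))
  cur <- start
  for (k in seq_len(nrow(be))) {
    loop[k] <- cur
    cur <- nxt[[as.character(cur)]]
    if (is.null(cur)) stop("boundary is not a single loop", call. = FALSE)
  }
  if (cur != start) stop("surface has more than one boundary loop", call. = FALSE)
  loop
}

#' Enclosed volume of a watertight triangle surface
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' triangles.
#' @param surface list with `vertices`, `triangles`.
#' @export
mesh_volume <- function(surface) {
  p <- tri_corner_coords(surface$vertices, surface$triangles)
  sum(rowSums(p$p1 * cross3(p$p2, p$p3))) / 6
}

# ---------------------------------------------------------------------------
# Polar disc triangulation with inward angular coarsening.  Boundary ring
# has n_theta vertices; the angular count halves as rings shrink so
# triangle sizes stay roughly uniform.  Used as the combinatorial domain
# for septal surfaces and (mapped to a hemisphere) for the end caps.
# ---------------------------------------------------------------------------

disc_mesh <- function(n_theta, n_rings = NULL, coarsen = TRUE, min_n = 8L,
                      rho = NULL) {
  stopifnot(n_theta >= 3)
  if (is.null(rho)) {
    stopifnot(n_rings >= 1)
    rho <- seq(1, 0, length.out = n_rings + 1L)[seq_len(n_rings)]
  } else {
    stopifnot(all(diff(rho) < 0), rho[1] <= 1, min(rho) > 0)
    if (rho[1] < 1) rho <- c(1, rho)
    n_rings <- length(rho)
  }
  gaps <- c(-diff(c(rho, 0)))
  counts <- integer(n_rings)  # ring 1 = boundary (rho = 1)
  n <- as.integer(n_theta)
  for (k in seq_len(n_rings)) {
    if (coarsen && k > 1L) {
      arc <- 2 * pi * rho[k] / n
      if (arc < 0.75 * gaps[k - 1L] && n %% 2L == 0L && n >= 2L * min_n) {
        n <- n %/% 2L
      }
    }
    counts[k] <- n
  }
  nv <- sum(counts) + 1L  # + centre
  P <- matrix(0, nv, 2)
  ring_of <- integer(nv)
  offs <- cumsum(c(0L, counts))
  for (k in seq_len(n_rings)) {
    j <- seq_len(counts[k]) - 1L
    ang <- 2 * pi * j / counts[k]
    idx <- offs[k] + j + 1L
    P[idx, ] <- cbind(rho[k] * cos(ang), rho[k] * sin(ang))
    ring_of[idx] <- k
  }
  centre <- nv
  ring_of[centre] <- n_rings + 1L
  tris <- vector("list", n_rings)
  for (k in seq_len(n_rings)) {
    no <- counts[k]
    oidx <- offs[k] + seq_len(no)
    if (k < n_rings) {
      ni <- counts[k + 1L]
      iidx <- offs[k + 1L] + seq_len(ni)
    } else {
      ni <- 1L
      iidx <- centre
    }
    if (ni == no) {
      j <- seq_len(no)
      jn <- c(2:no, 1L)
      tris[[k]] <- rbind(cbind(oidx[j], oidx[jn], iidx[j]),
                         cbind(oidx[jn], iidx[jn], iidx[j]))
    } else if (ni == 1L) {
      j <- seq_len(no)
      jn <- c(2:no, 1L)
      tris[[k]] <- cbind(oidx[j], oidx[jn], centre)
    } else if (no == 2L * ni) {
      j <- seq_len(ni)
      jn <- c(2:ni, 1L)
      o1 <- oidx[2L * j - 1L]         # aligned with inner j
      o2 <- oidx[2L * j]
      o3 <- oidx[c(2L * j + 1L)[seq_len(ni - 1L)]]
      o3 <- c(o3, oidx[1L])
      tris[[k]] <- rbind(cbind(o1, o2, iidx[j]),
                         cbind(o2, iidx[jn], iidx[j]),
                         cbind(o2, o3, iidx[jn]))
    } else {
      stop("unsupported ring reduction", call. = FALSE)
    }
  }
  F <- do.call(rbind, tris)
  storage.mode(F) <- "integer"
  list(param = P, triangles = F, ring = ring_of,
       counts = counts, boundary = seq_len(counts[1]))
}

# ---------------------------------------------------------------------------
# ASCII STL / legacy VTK writers (plain-text interchange)
# ---------------------------------------------------------------------------

#' Write a triangle surface as ASCII STL
#' @param surface list with `vertices`, `triangles`.
#' @param path output file.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(surface, path, name = "surface") {
  V <- surface$vertices; F <- surface$triangles
  n <- tri_face_normals(V, F)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (t in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[t, 1], n[t, 2], n[t, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- V[F[t, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a surface or tetrahedral mesh as legacy ASCII VTK
#'
#' Optional point data arrays (numeric vectors or 3-column matrices, or a
#' 6-column stress matrix written as a tensor) are attached as POINT_DATA.
#' @param mesh list with `vertices`/`nodes` and `triangles` or `tets`.
#' @param path output file.
#' @param point_data named list of per-vertex arrays.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  V <- if (!is.null(mesh$vertices)) mesh$vertices else mesh$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "phragmoFEM mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(V)), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  if (!is.null(mesh$tets)) {
    C <- mesh$tets; ctype <- 10L; npc <- 4L
  } else {
    C <- mesh$triangles; ctype <- 5L; npc <- 3L
  }
  writeLines(sprintf("CELLS %d %d", nrow(C), nrow(C) * (npc + 1L)), con)
  writeLines(do.call(sprintf, c(list(paste0("%d", strrep(" %d", npc))),
                                list(rep(npc, nrow(C))),
                                lapply(seq_len(npc), function(k) C[, k] - 1L))), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(C)), con)
  writeLines(as.character(rep(ctype, nrow(C))), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(V)), con)
    for (nm in names(point_data)) {
      a <- point_data[[nm]]
      if (is.null(dim(a))) {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(sprintf("%.9g", a), con)
      } else if (ncol(a) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]), con)
      } else if (ncol(a) == 6) {
        writeLines(sprintf("TENSORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g %.9g\n%.9g %.9g %.9g\n%.9g %.9g %.9g\n",
                           a[, 1], a[, 4], a[, 6],
                           a[, 4], a[, 2], a[, 5],
                           a[, 6], a[, 5], a[, 3]), con)
      }
    }
  }
  invisible(path)
}

#' Write a tetrahedral mesh in Gmsh MSH 2.2 ASCII format
#' @param mesh an `fe_mesh` (nodes, tets, element regions).
#' @param path output file.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$tets))), con)
  reg <- as.integer(factor(mesh$element_region))
  if (ncol(mesh$tets) == 4L) {
    writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(mesh$tets)),
                       reg, reg, mesh$tets[, 1], mesh$tets[, 2],
                       mesh$tets[, 3], mesh$tets[, 4]), con)
  } else {
    writeLines(sprintf("%d 11 2 %d %d %d %d %d %d %d %d %d %d %d %d",
                       seq_len(nrow(mesh$tets)), reg, reg,
                       mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                       mesh$tets[, 4], mesh$tets[, 5], mesh$tets[, 6],
                       mesh$tets[, 7], mesh$tets[, 8], mesh$tets[, 9],
                       mesh$tets[, 10]), con)
  }
  writeLines("$EndElements", con)
  invisible(path)
}
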