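# ---------------------------------------------------------------------------
# Linear isotropic elasticity on tetrahedral meshes: stiffness assembly
# (Rcpp kernels), consistent pressure loads, minimal rigid-body constraints,
# sparse Cholesky solve and stress recovery.  Units: mm, MPa, N, mJ.
# ---------------------------------------------------------------------------

# assemble the global stiffness matrix in element chunks
assemble_stiffness <- function(mesh, material, chunk = NULL) {
  ndof <- 3L * nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  npe <- ncol(mesh$tets)
  if (is.null(chunk)) chunk <- if (npe == 10L) 6000L else 40000L
  K <- NULL
  start <- 1L
  while (start <= m) {
    end <- min(start + chunk - 1L, m)
    tri <- tet_stiffness_batch(mesh$nodes, mesh$tets[start:end, , drop = FALSE],
                               material$E, material$nu)
    Kc <- Matrix::sparseMatrix(i = as.integer(tri$i), j = as.integer(tri$j),
                               x = as.numeric(tri$x), dims = c(ndof, ndof))
    K <- if (is.null(K)) Kc else K + Kc
    start <- end + 1L
  }
  Matrix::forceSymmetric(K, uplo = "L")
}

#' Consistent nodal forces for a uniform external pressure
#'
#' Applies pressure along the inward normal of every external facet
#' (outward-oriented 3-node or straight-sided 6-node triangles).  For
#' quadratic facets the consistent load places the whole facet force on the
#' midside nodes (the corner shape functions integrate to zero on a
#' straight triangle).
#'
#' @param mesh an `fe_mesh`.
#' @param pressure magnitude, MPa (positive = compressing the solid).
#' @return force vector of length `3 * n_nodes` (N).
#' @export
pressure_load <- function(mesh, pressure) {
  facets <- mesh$external
  V <- mesh$nodes
  n <- tri_face_normals(V, facets[, 1:3, drop = FALSE], normalize = FALSE)
  # n has magnitude 2A and points outward; total facet force = -P * A * nhat
  ftot <- -pressure * n / 2
  f <- numeric(3L * nrow(V))
  target <- if (ncol(facets) == 6L) facets[, 4:6, drop = FALSE] else
    facets[, 1:3, drop = FALSE]
  for (k in 1:3) {
    for (c in 1:3) {
      idx <- 3L * (target[, k] - 1L) + c
      acc <- rowsum(ftot[, c] / 3, idx)
      ids <- as.numeric(rownames(acc))
      f[ids] <- f[ids] + acc
    }
  }
  f
}

#' Minimal rigid-body constraints (3-2-1 rule)
#'
#' Selects three well-separated, non-collinear corner nodes and fixes
#' 3 + 2 + 1 axis-aligned displacement components chosen so that exactly
#' the six rigid-body modes are removed; the combination with the best
#' conditioning on the rigid-mode space is used.  For a self-equilibrated
#' pressure load the constraint reactions are (numerically) zero.
#'
#' @param mesh an `fe_mesh`.
#' @param nodes optional integer vector of three node ids to use.
#' @return list with `nodes`, `dofs` (global dof indices) and the rigid
#'   mode condition number.
#' @export
constrain_rigid_body <- function(mesh, nodes = NULL) {
  V <- mesh$nodes
  nc <- if (!is.null(mesh$n_corner)) mesh$n_corner else nrow(V)
  if (is.null(nodes)) {
    cen <- colMeans(V[seq_len(nc), , drop = FALSE])
    d <- sweep(V[seq_len(nc), , drop = FALSE], 2, cen)
    A <- which.max(rowSums(d^2))
    dA <- sweep(V[seq_len(nc), , drop = FALSE], 2, V[A, ])
    B <- which.max(rowSums(dA^2))
    ab <- V[B, ] - V[A, ]
    ab <- ab / sqrt(sum(ab^2))
    dline <- dA - outer(c(dA %*% ab), ab)
    C <- which.max(rowSums(dline^2))
    nodes <- c(A, B, C)
  }
  if (length(unique(nodes)) < 3) stop("need 3 distinct nodes", call. = FALSE)
  rigid_row <- function(node, axis) {
    p <- V[node, ]
    tr <- c(axis == 1, axis == 2, axis == 3)
    rot <- switch(axis,
                  c(0, p[3], -p[2]),   # (omega x p)_x per unit omega
                  c(-p[3], 0, p[1]),
                  c(p[2], -p[1], 0))
    c(tr, rot)
  }
  best <- NULL; best_rc <- -Inf
  for (drop_b in 1:3) {
    for (c_axis in 1:3) {
      b_axes <- setdiff(1:3, drop_b)
      R <- rbind(rigid_row(nodes[1], 1), rigid_row(nodes[1], 2),
                 rigid_row(nodes[1], 3),
                 rigid_row(nodes[2], b_axes[1]), rigid_row(nodes[2], b_axes[2]),
                 rigid_row(nodes[3], c_axis))
      rc <- rcond(R)
      if (rc > best_rc) {
        best_rc <- rc
        best <- list(b_axes = b_axes, c_axis = c_axis)
      }
    }
  }
  if (best_rc < 1e-12) stop("could not find independent rigid-body constraints",
                            call. = FALSE)
  dofs <- c(3L * (nodes[1] - 1L) + 1:3,
            3L * (nodes[2] - 1L) + best$b_axes,
            3L * (nodes[3] - 1L) + best$c_axis)
  list(nodes = nodes, dofs = sort(dofs), rcond = best_rc)
}

#' Solve the linear elastic pressure problem
#'
#' Displacement-based FEM on linear or quadratic tetrahedra: assembles the
#' isotropic stiffness, applies the external pressure as consistent facet
#' tractions, removes rigid-body modes, solves the sparse SPD system by
#' Cholesky factorisation, and recovers element and nodal stresses.
#'
#' @param mesh an `fe_mesh` from [tet_mesh()] or a fixture generator.
#' @param material a [material_params()]; defaults to the mesh config's.
#' @param pressure external pressure, MPa; defaults to the config's.
#' @param constraints optional result of [constrain_rigid_body()].
#' @param extra_fixed_dofs additional global dof indices to pin to zero
#'   (e.g. plane-strain conditions in validation fixtures).
#' @param load optional replacement force vector.
#' @return an `elastic_solution`: nodal displacements `u` (mm), element
#'   centroid stresses, nodal (extrapolated, volume-weighted) stresses,
#'   strain energy (mJ), reactions and diagnostics.
#' @export
solve_elastic <- function(mesh, material = NULL, pressure = NULL,
                          constraints = NULL, extra_fixed_dofs = integer(0),
                          load = NULL) {
  if (is.null(material)) material <- mesh$config$material
  if (is.null(material)) material <- material_params()
  if (is.null(pressure)) pressure <- mesh$config$pressure
  ndof <- 3L * nrow(mesh$nodes)
  K <- assemble_stiffness(mesh, material)
  f <- if (is.null(load)) pressure_load(mesh, pressure) else load
  if (is.null(constraints)) constraints <- constrain_rigid_body(mesh)
  fixed <- sort(unique(c(constraints$dofs, as.integer(extra_fixed_dofs))))
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free]
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                 error = function(e) {
                   stop("stiffness not positive definite after constraints: ",
                        conditionMessage(e), call. = FALSE)
                 })
  ufree <- as.numeric(Matrix::solve(ch, f[free], system = "A"))
  rm(ch, Kff)
  gc(verbose = FALSE)
  u <- numeric(ndof)
  u[free] <- ufree
  resid <- as.numeric(K %*% u - f)
  reactions <- resid[fixed]
  strain_energy <- 0.5 * sum(f * u)
  st <- tet_stress_batch(mesh$nodes, mesh$tets, u, material$E, material$nu)
  nodal <- recover_nodal_stress_matrix(mesh, st)
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 stress_element = st[, 25:30, drop = FALSE],
                 stress_corner = st[, 1:24, drop = FALSE],
                 stress_nodes = nodal,
                 strain_energy = strain_energy,
                 reactions = reactions,
                 fixed_dofs = fixed,
                 pressure = pressure, material = material,
                 diagnostics = list(
                   ndof = ndof,
                   total_traction = sum(abs(f)),
                   max_reaction = if (length(reactions)) max(abs(reactions)) else 0,
                   residual_inf = max(abs(resid[free])))),
            class = "elastic_solution")
}

#' @export
print.elastic_solution <- function(x, ...) {
  cat(sprintf("<elastic_solution: %d dofs, strain energy %.4g mJ, max |u| %.4g mm>\n",
              x$diagnostics$ndof, x$strain_energy, max(abs(x$u))))
  invisible(x)
}

# nodal stress by volume-weighted averaging of the element stress field
# evaluated at each corner node (extrapolated recovery, as stress output at
# nodes); midside nodes inherit the mean of their edge endpoints
recover_nodal_stress_matrix <- function(mesh, st = NULL, u = NULL,
                                        material = NULL) {
  if (is.null(st)) {
    st <- tet_stress_batch(mesh$nodes, mesh$tets, u, material$E, material$nu)
  }
  vol <- abs(as.numeric(tet_volumes(mesh$nodes, mesh$tets[, 1:4, drop = FALSE])))
  nnode <- nrow(mesh$nodes)
  acc <- matrix(0, nnode, 6)
  wsum <- numeric(nnode)
  for (c in 1:4) {
    ids <- mesh$tets[, c]
    w <- rowsum(vol, ids)
    widx <- as.integer(rownames(w))
    wsum[widx] <- wsum[widx] + w
    block <- st[, (6 * (c - 1) + 1):(6 * c), drop = FALSE] * vol
    sacc <- rowsum(block, ids)
    acc[widx, ] <- acc[widx, ] + sacc
  }
  got <- wsum > 0
  acc[got, ] <- acc[got, ] / wsum[got]
  if (!is.null(mesh$edge_ends)) {
    mid <- (acc[mesh$edge_ends[, 1], , drop = FALSE] +
              acc[mesh$edge_ends[, 2], , drop = FALSE]) / 2
    acc[(mesh$n_corner + 1):nnode, ] <- mid
  }
  colnames(acc) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  acc
}

#' Recover nodal stress tensors from a solved state
#'
#' Volume-weighted average over adjacent elements of the element stress
#' field evaluated at the node; element-level values are retained in the
#' solution object.
#' @param solution an `elastic_solution`.
#' @param mesh the `fe_mesh` it was solved on.
#' @return matrix `n_nodes x 6` (Voigt xx, yy, zz, xy, yz, zx), MPa.
#' @export
recover_nodal_stress <- function(solution, mesh) {
  recover_nodal_stress_matrix(
    mesh, cbind(solution$stress_corner, solution$stress_element))
}

#' Scale a linear solution to another pressure
#'
#' In the linear model every displacement and stress component scales with
#' the load and the strain energy with its square, so pressure series can
#' be derived from one reference solve.
#' @param solution an `elastic_solution`.
#' @param pressure new pressure, MPa.
#' @export
scale_solution <- function(solution, pressure) {
  s <- pressure / solution$pressure
  out <- solution
  out$u <- solution$u * s
  out$stress_element <- solution$stress_element * s
  out$stress_corner <- solution$stress_corner * s
  out$stress_nodes <- solution$stress_nodes * s
  out$strain_energy <- solution$strain_energy * s^2
  out$reactions <- solution$reactions * s
  out$pressure <- pressure
  out
}
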