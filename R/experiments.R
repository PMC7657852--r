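# ---------------------------------------------------------------------------
# Experiment driver: the 11-model reference suite (septal spacing, shell
# thickness, lobate complexity, Koch iterations), pressure series, and
# analytic validation fixtures.
# ---------------------------------------------------------------------------

# boundary faces of a tet mesh (faces belonging to exactly one element)
boundary_faces_of_tets <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  srt <- t(apply(faces, 1, sort))
  key <- paste(srt[, 1], srt[, 2], srt[, 3])
  faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

new_fixture_mesh <- function(nodes, prisms, region, pressure, material,
                             order = 2L, config = NULL) {
  tets <- split_prisms(prisms)
  vol <- as.numeric(tet_volumes(nodes, tets))
  neg <- vol < 0
  if (any(neg)) tets[neg, ] <- tets[neg, c(2, 1, 3, 4)]
  external <- boundary_faces_of_tets(tets)
  # orient outward: centroid ray test about the mesh centroid
  cen <- colMeans(nodes)
  fc <- (nodes[external[, 1], ] + nodes[external[, 2], ] +
           nodes[external[, 3], ]) / 3
  fn <- tri_face_normals(nodes, external, normalize = FALSE)
  flip <- rowSums(fn * sweep(fc, 2, cen)) < 0
  external[flip, ] <- external[flip, c(1, 3, 2)]
  if (is.null(config)) {
    config <- list(pressure = pressure, material = material)
  }
  out <- structure(list(nodes = nodes, tets = tets,
                        element_region = rep(region, length.out = nrow(tets)),
                        external = external, node_meta = NULL, order = 1L,
                        n_corner = nrow(nodes), edge_ends = NULL,
                        config = config, solid = NULL,
                        quality = list(n_elements = nrow(tets),
                                       n_nodes = nrow(nodes),
                                       min_volume = min(abs(vol)),
                                       total_volume = sum(abs(vol)),
                                       n_inverted = 0L)),
                   class = "fe_mesh")
  if (order == 2L) out <- promote_to_quadratic(out)
  out
}

# structured box mesh, hexes split into two prisms each
box_mesh <- function(nx = 3L, ny = 3L, nz = 3L, lx = 1, ly = 1, lz = 1,
                     pressure = 2, material = material_params(), order = 2L) {
  id <- function(i, j, k) ((k - 1L) * (ny + 1L) + (j - 1L)) * (nx + 1L) + i
  g <- expand.grid(i = seq_len(nx + 1L), j = seq_len(ny + 1L),
                   k = seq_len(nz + 1L))
  nodes <- cbind((g$i - 1) / nx * lx, (g$j - 1) / ny * ly, (g$k - 1) / nz * lz)
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  v1 <- id(cells$i, cells$j, cells$k)
  v2 <- id(cells$i + 1L, cells$j, cells$k)
  v3 <- id(cells$i + 1L, cells$j + 1L, cells$k)
  v4 <- id(cells$i, cells$j + 1L, cells$k)
  up <- (ny + 1L) * (nx + 1L)
  prisms <- rbind(cbind(v1, v2, v3, v1 + up, v2 + up, v3 + up),
                  cbind(v1, v3, v4, v1 + up, v3 + up, v4 + up))
  storage.mode(prisms) <- "integer"
  new_fixture_mesh(nodes, prisms, "box", pressure, material, order)
}

# structured annular cylinder (no caps); external facets filtered to the
# requested surfaces when loading
annulus_mesh <- function(r_in = 5, r_out = 10, height = 2, n_theta = 64L,
                         n_radial = 4L, n_axial = 2L, pressure = 2,
                         material = material_params(), order = 2L) {
  nt <- as.integer(n_theta); nr <- as.integer(n_radial); nz <- as.integer(n_axial)
  theta <- 2 * pi * (seq_len(nt) - 1L) / nt
  radii <- seq(r_in, r_out, length.out = nr + 1L)
  zl <- seq(0, height, length.out = nz + 1L)
  id <- function(i, j, k) ((k - 1L) * nt + (j - 1L)) * (nr + 1L) + i + 1L
  g <- expand.grid(i = 0:nr, j = seq_len(nt), k = seq_len(nz + 1L))
  nodes <- cbind(radii[g$i + 1L] * cos(theta[g$j]),
                 radii[g$i + 1L] * sin(theta[g$j]), zl[g$k])
  jn <- c(2:nt, 1L)
  quads <- expand.grid(j = seq_len(nt), k = seq_len(nz))
  tris <- rbind(cbind(quads$j, jn[quads$j], jn[quads$j], quads$k, quads$k, quads$k + 1L),
                cbind(quads$j, jn[quads$j], quads$j, quads$k, quads$k + 1L, quads$k + 1L))
  blocks <- list()
  for (i in seq_len(nr)) {
    bot <- cbind(id(i - 1L, tris[, 1], tris[, 4]),
                 id(i - 1L, tris[, 2], tris[, 5]),
                 id(i - 1L, tris[, 3], tris[, 6]))
    top <- cbind(id(i, tris[, 1], tris[, 4]),
                 id(i, tris[, 2], tris[, 5]),
                 id(i, tris[, 3], tris[, 6]))
    blocks[[i]] <- cbind(bot, top)
  }
  prisms <- do.call(rbind, blocks)
  storage.mode(prisms) <- "integer"
  mesh <- new_fixture_mesh(nodes, prisms, "annulus", pressure, material,
                           order = 1L)
  # keep only outer-lateral facets for the pressure load
  fc <- (mesh$nodes[mesh$external[, 1], ] + mesh$nodes[mesh$external[, 2], ] +
           mesh$nodes[mesh$external[, 3], ]) / 3
  rr <- sqrt(fc[, 1]^2 + fc[, 2]^2)
  mesh$external <- mesh$external[rr > r_out - 0.26 * (r_out - r_in) / nr, ,
                                 drop = FALSE]
  if (order == 2L) mesh <- promote_to_quadratic(mesh)
  mesh
}

# closed thin spherical shell from two hemispherical disc meshes sharing
# the equator ring
sphere_mesh <- function(r_in = 9.95, r_out = 10.05, n_theta = 64L,
                        n_rings = 12L, n_radial = 1L, pressure = 2,
                        material = material_params(), order = 2L) {
  nt <- as.integer(n_theta); nr <- as.integer(n_radial)
  dm <- disc_mesh(nt, n_rings)
  nv <- nrow(dm$param)
  rho <- sqrt(rowSums(dm$param^2))
  ang <- atan2(dm$param[, 2], dm$param[, 1])
  phi <- rho * pi / 2
  radii <- seq(r_in, r_out, length.out = nr + 1L)
  interior <- setdiff(seq_len(nv), dm$boundary)
  # layer-major ids: equator ring shared between hemispheres
  n_eq <- nt * (nr + 1L)
  eq_id <- function(i, j) (j - 1L) * (nr + 1L) + i + 1L
  nodes <- matrix(0, n_eq, 3)
  for (i in 0:nr) {
    j <- seq_len(nt)
    nodes[eq_id(i, j), ] <- cbind(radii[i + 1L] * cos(ang[j]),
                                  radii[i + 1L] * sin(ang[j]), 0)
  }
  maps <- list(top = vector("list", nr + 1L), bottom = vector("list", nr + 1L))
  blocks <- list(nodes)
  next_id <- n_eq
  for (side in c("top", "bottom")) {
    sgn <- if (side == "top") 1 else -1
    for (i in 0:nr) {
      ids <- integer(nv)
      ids[dm$boundary] <- eq_id(i, seq_len(nt))
      pts <- cbind(radii[i + 1L] * sin(phi[interior]) * cos(ang[interior]),
                   radii[i + 1L] * sin(phi[interior]) * sin(ang[interior]),
                   sgn * radii[i + 1L] * cos(phi[interior]))
      ids[interior] <- next_id + seq_along(interior)
      next_id <- next_id + length(interior)
      blocks[[length(blocks) + 1L]] <- pts
      maps[[side]][[i + 1L]] <- ids
    }
  }
  nodes <- do.call(rbind, blocks)
  Fd <- dm$triangles
  pblocks <- list()
  for (side in c("top", "bottom")) {
    for (i in seq_len(nr)) {
      m0 <- maps[[side]][[i]]; m1 <- maps[[side]][[i + 1L]]
      pblocks[[length(pblocks) + 1L]] <-
        cbind(m0[Fd[, 1]], m0[Fd[, 2]], m0[Fd[, 3]],
              m1[Fd[, 1]], m1[Fd[, 2]], m1[Fd[, 3]])
    }
  }
  prisms <- do.call(rbind, pblocks)
  storage.mode(prisms) <- "integer"
  mesh <- new_fixture_mesh(nodes, prisms, "sphere", pressure, material,
                           order = 1L)
  fc <- (mesh$nodes[mesh$external[, 1], ] + mesh$nodes[mesh$external[, 2], ] +
           mesh$nodes[mesh$external[, 3], ]) / 3
  rr <- sqrt(rowSums(fc^2))
  mesh$external <- mesh$external[rr > (r_in + r_out) / 2, , drop = FALSE]
  if (order == 2L) mesh <- promote_to_quadratic(mesh)
  mesh
}

#' Analytic validation fixtures
#'
#' Small geometries paired with their closed-form elastic truth, used as
#' independent oracles for the solver and surface fitter:
#' `hydrostatic_cube` (uniform stress -P I), `lame_cylinder` (thick-wall
#' plane-strain hoop/radial profiles), `pressurized_sphere` (membrane
#' stress P r / (2 t)), `capped_cylinder` (thin-wall hoop P r / t on a
#' septa-free shell), `flat_disc_boundary` (planar circular suture whose
#' minimum-curvature surface is exactly flat).
#'
#' @param name fixture name.
#' @param ... geometry overrides (`r_in`, `r_out`, `pressure`, mesh sizes).
#' @return list with `mesh` (or `curve`), `truth` (function or scalar) and
#'   a description.
#' @export
make_fixture <- function(name = c("hydrostatic_cube", "lame_cylinder",
                                  "pressurized_sphere", "capped_cylinder",
                                  "flat_disc_boundary"), ...) {
  name <- match.arg(name)
  args <- list(...)
  P <- if (!is.null(args$pressure)) args$pressure else 2
  switch(name,
    hydrostatic_cube = {
      mesh <- box_mesh(nx = 2L, ny = 2L, nz = 2L, pressure = P,
                       order = if (!is.null(args$order)) args$order else 2L)
      list(name = name, mesh = mesh,
           truth = c(xx = -P, yy = -P, zz = -P, xy = 0, yz = 0, zx = 0),
           description = "uniform hydrostatic compression -P*I")
    },
    lame_cylinder = {
      ri <- if (!is.null(args$r_in)) args$r_in else 5
      ro <- if (!is.null(args$r_out)) args$r_out else 10
      mesh <- annulus_mesh(r_in = ri, r_out = ro, pressure = P,
                           n_theta = if (!is.null(args$n_theta)) args$n_theta else 64L,
                           n_radial = if (!is.null(args$n_radial)) args$n_radial else 6L)
      hoop <- function(r) -P * ro^2 * (1 + ri^2 / r^2) / (ro^2 - ri^2)
      radial <- function(r) -P * ro^2 * (1 - ri^2 / r^2) / (ro^2 - ri^2)
      list(name = name, mesh = mesh,
           truth = list(hoop = hoop, radial = radial),
           description = "thick-walled cylinder under external pressure (plane strain)")
    },
    pressurized_sphere = {
      ri <- if (!is.null(args$r_in)) args$r_in else 9.95
      ro <- if (!is.null(args$r_out)) args$r_out else 10.05
      mesh <- sphere_mesh(r_in = ri, r_out = ro, pressure = P)
      rm <- (ri + ro) / 2; t <- ro - ri
      list(name = name, mesh = mesh,
           truth = -P * rm / (2 * t),
           description = "thin spherical shell membrane stress P*r/(2t)")
    },
    capped_cylinder = {
      cfg <- model_config(
        inner_radius = if (!is.null(args$r)) args$r else 9.11,
        shell_thickness = if (!is.null(args$t)) args$t else 0.5,
        n_septa = 0L, pressure = P)
      mesh_opt <- if (!is.null(args$mesh)) args$mesh else mesh_options()
      solid <- build_shell(cfg, mesh_opt)
      list(name = name, mesh = tet_mesh(solid),
           truth = hoop_stress_theory(P, cfg$inner_radius, cfg$shell_thickness),
           description = "septa-free capped cylinder; thin-wall hoop P*r/t")
    },
    flat_disc_boundary = {
      r <- if (!is.null(args$r)) args$r else 5
      n <- if (!is.null(args$n)) args$n else 96L
      x <- (seq_len(n) - 1) / n
      curve <- new_planar_curve(cbind(x = x, y = rep(0, n)), periodic = TRUE)
      suture <- wrap_on_cylinder(curve, radius = r)
      list(name = name, curve = suture, truth = 0,
           description = "planar circular boundary; flat disc is the exact minimiser")
    })
}

# ---------------------------------------------------------------------------
# The reference model suite
# ---------------------------------------------------------------------------

#' Mesh resolution tiers
#'
#' `"coarse"` is sized for desk-scale runs (validation errors of a few
#' percent, directional comparisons resolved); `"fine"` doubles the
#' resolution for convergence studies.
#' @param tier `"coarse"` or `"fine"`.
#' @param family suture family the model uses.
#' @export
tier_mesh <- function(tier = c("coarse", "fine"),
                      family = c("lobate", "koch")) {
  tier <- match.arg(tier)
  family <- match.arg(family)
  if (family == "lobate") {
    if (tier == "coarse") mesh_options(n_theta = 96L, target_size = 1.6)
    else mesh_options(n_theta = 192L, target_size = 0.8)
  } else {
    if (tier == "coarse") {
      mesh_options(n_theta = 160L, target_size = 4, septum_rings = 10L,
                   cap_rings = 6L)
    } else {
      mesh_options(n_theta = 384L, target_size = 1.1, septum_rings = 20L)
    }
  }
}

#' The 11-model reference suite
#'
#' Named model configurations covering the four experiments: septal
#' spacing (sexilobate at 5/10/20 mm), shell thickness (trilobate and
#' sexilobate at 0.1 vs 0.5 mm), lobate complexity (3--6 lobes) and Koch
#' iterations (1--3, solved at 1/2/3 MPa).
#' @param tier mesh resolution tier.
#' @return named list; each entry has `config`, `mesh`, `pressures`.
#' @export
reference_suite <- function(tier = "coarse") {
  lob <- function(n) suture_spec("lobate", n_lobes = n)
  koch <- function(it) suture_spec("koch", iterations = it, n_copies = 4L)
  entry <- function(config, family, pressures = 2) {
    list(config = config, mesh = tier_mesh(tier, family),
         pressures = pressures)
  }
  list(
    sexilobate = entry(model_config(suture = lob(6L)), "lobate"),
    sexilobate_s10 = entry(model_config(septal_spacing = 10, suture = lob(6L)),
                           "lobate"),
    sexilobate_s20 = entry(model_config(septal_spacing = 20, suture = lob(6L)),
                           "lobate"),
    trilobate = entry(model_config(suture = lob(3L)), "lobate"),
    trilobate_thin = entry(model_config(shell_thickness = 0.1,
                                        suture = lob(3L)), "lobate"),
    sexilobate_thin = entry(model_config(shell_thickness = 0.1,
                                         suture = lob(6L)), "lobate"),
    quadrilobate = entry(model_config(suture = lob(4L)), "lobate"),
    quinquelobate = entry(model_config(suture = lob(5L)), "lobate"),
    koch_i1 = entry(model_config(suture = koch(1L)), "koch", c(1, 2, 3)),
    koch_i2 = entry(model_config(suture = koch(2L)), "koch", c(1, 2, 3)),
    koch_i3 = entry(model_config(suture = koch(3L)), "koch", c(1, 2, 3))
  )
}

config_signature <- function(config, mesh) {
  su <- config$suture
  paste(config$inner_radius, config$shell_thickness, config$septal_spacing,
        config$n_septa, su$family, su$n_lobes, su$iterations, su$n_copies,
        round(su$amplitude, 6), config$septal_thickness, config$end_margin,
        mesh$n_theta, mesh$target_size, mesh$order, sep = "|")
}

#' Build, solve and post-process one model
#'
#' Runs the full pipeline for one configuration: assembly, tetrahedral
#' meshing, one reference linear solve, and (by linearity) exact rescaling
#' to the requested pressure series.  Returns the per-pressure results
#' table and the middle-septum line probe.
#'
#' @param config a [model_config()].
#' @param mesh a [mesh_options()].
#' @param pressures pressure series, MPa.
#' @param name model label for the results table.
#' @param keep_solution retain the solution and mesh in the output.
#' @export
run_model <- function(config, mesh = mesh_options(), pressures = 2,
                      name = "model", keep_solution = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  solid <- build_shell(config, mesh)
  fem <- tet_mesh(solid)
  t_build <- proc.time()[["elapsed"]] - t0
  ref_p <- max(pressures)
  sol <- solve_elastic(fem, pressure = ref_p)
  t_solve <- proc.time()[["elapsed"]] - t0 - t_build
  probe <- line_probe(sol, fem)
  verr <- validation_error(sol, fem)
  rows <- lapply(pressures, function(p) {
    s <- scale_solution(sol, p)
    wall <- region_stats(s, fem, "shell_wall", pressure = p)
    sep <- if (config$n_septa > 0) region_stats(s, fem, "septum", pressure = p)
      else data.frame(mean_MPa = NA, sd_MPa = NA, peak_MPa = NA)
    disp <- if (config$n_septa > 0) septum_centre_displacement(s, fem) else NA
    pr <- line_probe(s, fem)
    mid_z <- if (config$n_septa > 0)
      solid$z_septa[ceiling(config$n_septa / 2)] else 0
    band <- abs(pr$z_mm - mid_z) <= config$septal_spacing
    data.frame(
      model = name, pressure_MPa = p,
      family = config$suture$family,
      complexity = if (config$suture$family == "koch")
        config$suture$iterations else config$suture$n_lobes,
      spacing_mm = config$septal_spacing,
      wall_mm = config$shell_thickness,
      wall_mean_MPa = wall$mean_MPa, wall_sd_MPa = wall$sd_MPa,
      wall_peak_MPa = wall$peak_MPa,
      septum_mean_MPa = sep$mean_MPa, septum_sd_MPa = sep$sd_MPa,
      septum_peak_MPa = sep$peak_MPa,
      probe_peak_tangential_MPa = max(abs(pr$tangential_MPa[band])),
      probe_mean_tangential_MPa = mean(abs(pr$tangential_MPa[band])),
      strain_energy_mJ = s$strain_energy,
      centre_disp_um = disp,
      validation_pct = verr,
      n_elements = fem$quality$n_elements,
      n_nodes = fem$quality$n_nodes,
      build_s = round(t_build, 2), solve_s = round(t_solve, 2),
      config_sig = config_signature(config, resolve_mesh(config, mesh)),
      stringsAsFactors = FALSE)
  })
  out <- list(results = do.call(rbind, rows), probe = probe, name = name)
  if (keep_solution) {
    out$solution <- sol
    out$mesh <- fem
  }
  out
}

#' Run the model suite
#'
#' Drives build -> mesh -> solve -> post-processing for every model of a
#' suite specification, writing one results CSV and one probe CSV per
#' model under `out_dir`.  Completed models (existing CSVs with matching
#' configuration signatures) are skipped, so interrupted suites resume;
#' per-model failures are recorded without aborting the suite.  The
#' pipeline is fully deterministic.
#'
#' By default each model runs in its own short-lived R subprocess: the
#' larger models peak at a few GB during factorisation, and isolating
#' them returns that memory to the system between models instead of
#' accumulating allocator fragmentation over a long suite.
#'
#' @param suite a [reference_suite()]-style named list (possibly subset).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @param isolate run each model in a fresh subprocess.
#' @return combined results data.frame (also written as
#'   `suite_results.csv`).
#' @export
run_suite <- function(suite = reference_suite(), out_dir = "results/suite",
                      quiet = FALSE, isolate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_rows <- list()
  for (nm in names(suite)) {
    spec <- suite[[nm]]
    rfile <- file.path(out_dir, sprintf("model_%s.csv", nm))
    pfile <- file.path(out_dir, sprintf("probe_%s.csv", nm))
    sig <- config_signature(spec$config,
                            resolve_mesh(spec$config, spec$mesh))
    if (file.exists(rfile)) {
      rows <- read.csv(rfile, stringsAsFactors = FALSE)
      if (all(rows$config_sig == sig)) {
        if (!quiet) message("suite: ", nm, " (cached)")
        all_rows[[nm]] <- rows
        next
      }
    }
    if (!quiet) message("suite: ", nm)
    err <- if (isolate) {
      run_model_subprocess(spec, nm, rfile, pfile)
    } else {
      res <- tryCatch(
        run_model(spec$config, spec$mesh, spec$pressures, name = nm),
        error = function(e) conditionMessage(e))
      if (is.character(res)) res else {
        write.csv(res$results, rfile, row.names = FALSE)
        write.csv(res$probe, pfile, row.names = FALSE)
        rm(res); gc(verbose = FALSE, full = TRUE)
        NULL
      }
    }
    if (!is.null(err)) {
      warning("model ", nm, " failed: ", err, call. = FALSE)
      next
    }
    all_rows[[nm]] <- read.csv(rfile, stringsAsFactors = FALSE)
  }
  out <- if (length(all_rows)) do.call(rbind, all_rows) else data.frame()
  rownames(out) <- NULL
  write.csv(out, file.path(out_dir, "suite_results.csv"), row.names = FALSE)
  out
}

# run one suite entry in a fresh Rscript process (same library paths);
# returns NULL on success or an error message
run_model_subprocess <- function(spec, name, rfile, pfile) {
  spec_file <- tempfile(fileext = ".rds")
  saveRDS(list(spec = spec, name = name, rfile = rfile, pfile = pfile),
          spec_file)
  code <- sprintf(
    "x <- readRDS('%s'); library(phragmoFEM);
     res <- run_model(x$spec$config, x$spec$mesh, x$spec$pressures,
                      name = x$name);
     write.csv(res$results, x$rfile, row.names = FALSE);
     write.csv(res$probe, x$pfile, row.names = FALSE)", spec_file)
  script <- tempfile(fileext = ".R")
  writeLines(code, script)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c("--vanilla", shQuote(script)),
                    stdout = FALSE, stderr = FALSE,
                    env = paste0("R_LIBS=",
                                 paste(.libPaths(), collapse = .Platform$path.sep)))
  unlink(c(spec_file, script))
  if (status != 0 || !file.exists(rfile)) {
    return(sprintf("subprocess exit status %d", status))
  }
  NULL
}

#' Percent differences between two analysed models
#'
#' @param results a [run_suite()] results table.
#' @param model_a,model_b model names.
#' @param quantities numeric result columns to compare.
#' @param pressure pressure at which to compare, MPa.
#' @return data.frame of `quantity`, values and percent change (B vs A).
#' @export
compare_models <- function(results, model_a, model_b,
                           quantities = c("probe_peak_tangential_MPa",
                                          "wall_mean_MPa", "wall_peak_MPa"),
                           pressure = 2) {
  ra <- results[results$model == model_a & results$pressure_MPa == pressure, ]
  rb <- results[results$model == model_b & results$pressure_MPa == pressure, ]
  if (nrow(ra) != 1 || nrow(rb) != 1) {
    stop("models not analysed at the requested pressure", call. = FALSE)
  }
  do.call(rbind, lapply(quantities, function(q) {
    a <- ra[[q]]; b <- rb[[q]]
    data.frame(quantity = q, value_a = a, value_b = b,
               percent_change = (b - a) / abs(a) * 100,
               stringsAsFactors = FALSE)
  }))
}
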