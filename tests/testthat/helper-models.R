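# Shared solved models, built once per test run (everything is
# deterministic, so caching is safe).
.model_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, builder(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# small sexilobate model for probe/region plumbing tests (not tier-sized)
tiny_sexilobate <- function() {
  cached("tiny_sexilobate", function() {
    cfg <- model_config(suture = suture_spec("lobate", n_lobes = 6L))
    solid <- build_shell(cfg, mesh_options(n_theta = 48L, target_size = 3))
    fem <- tet_mesh(solid)
    list(config = cfg, solid = solid, mesh = fem,
         solution = solve_elastic(fem))
  })
}

# solved hydrostatic cube (order 2)
cube_solution <- function() {
  cached("cube", function() {
    fx <- make_fixture("hydrostatic_cube", pressure = 2)
    list(fixture = fx, solution = solve_elastic(fx$mesh))
  })
}

# regular (non-coarsened) spherical cap surface for curvature oracles
spherical_cap_surface <- function(R = 10, n_theta = 64L, n_rings = 16L,
                                  phi_max = pi / 3) {
  dm <- phragmoFEM:::disc_mesh(n_theta, n_rings, coarsen = FALSE)
  rho <- sqrt(rowSums(dm$param^2))
  ang <- atan2(dm$param[, 2], dm$param[, 1])
  phi <- rho * phi_max
  V <- cbind(R * sin(phi) * cos(ang), R * sin(phi) * sin(ang), R * cos(phi))
  list(vertices = V, triangles = dm$triangles, rho = rho)
}
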