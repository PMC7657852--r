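test_that("a hydrostatically loaded cube carries the exact uniform stress", {
  cs <- cube_solution()
  sol <- cs$solution
  err <- sweep(sol$stress_nodes, 2, cs$fixture$truth)
  expect_lt(max(abs(err)), 1e-6 * 2)
  # nodal recovery of a constant field equals the element values
  expect_lt(max(abs(sweep(sol$stress_element, 2, cs$fixture$truth))), 1e-6)
  # principal stresses of the hydrostatic state are all -P
  mp <- max_principal(sol$stress_nodes)
  expect_equal(range(mp), c(-2, -2), tolerance = 1e-6)
  # linear elements reproduce it too
  fx1 <- make_fixture("hydrostatic_cube", pressure = 2, order = 1L)
  s1 <- solve_elastic(fx1$mesh)
  expect_lt(max(abs(sweep(s1$stress_nodes, 2, fx1$truth))), 1e-6 * 2)
})

test_that("self-equilibrated pressure loads leave zero constraint reactions", {
  cs <- cube_solution()
  d <- cs$solution$diagnostics
  expect_lt(d$max_reaction, 1e-6 * d$total_traction)
  expect_equal(length(cs$solution$fixed_dofs), 6L)  # 3-2-1 rule
  expect_lt(d$residual_inf, 1e-8 * d$total_traction)
  expect_gt(cs$solution$strain_energy, 0)
})

test_that("stress scales linearly and energy quadratically with pressure", {
  cs <- cube_solution()
  s2 <- scale_solution(cs$solution, 4)
  fresh <- solve_elastic(cs$fixture$mesh, pressure = 4)
  expect_equal(s2$u, fresh$u, tolerance = 1e-10)
  expect_equal(s2$stress_nodes, fresh$stress_nodes, tolerance = 1e-10)
  expect_equal(s2$strain_energy, 4 * cs$solution$strain_energy,
               tolerance = 1e-12)
})

test_that("the thick-walled cylinder matches the Lame closed form", {
  fx <- make_fixture("lame_cylinder", pressure = 2)
  m <- fx$mesh
  nz_dofs <- seq(3L, 3L * nrow(m$nodes), by = 3L)  # plane strain
  pa <- which.min((m$nodes[, 1] - 5)^2 + m$nodes[, 2]^2 + m$nodes[, 3]^2)
  pb <- which.min((m$nodes[, 1] + 5)^2 + m$nodes[, 2]^2 + m$nodes[, 3]^2)
  cons <- list(dofs = c(3L * (pa - 1L) + 1:2, 3L * (pb - 1L) + 2L))
  sol <- solve_elastic(m, constraints = cons, extra_fixed_dofs = nz_dofs)
  rr <- sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)
  cyl <- to_cylindrical(sol$stress_nodes, m$nodes)
  inner <- which(abs(rr - 5) < 1e-6)
  expect_equal(mean(cyl$tangential[inner]), fx$truth$hoop(5),
               tolerance = 0.02)
  outer <- which(abs(rr - 10) < 1e-6)
  expect_equal(mean(cyl$radial[outer]), fx$truth$radial(10),
               tolerance = 0.02)
})

test_that("the stress field is insensitive to the constraint node choice", {
  tm <- tiny_sexilobate()
  mesh <- tm$mesh
  base <- tm$solution
  # alternative well-separated triple
  nc <- mesh$n_corner
  V <- mesh$nodes[seq_len(nc), ]
  alt <- c(which.max(V[, 1] + V[, 3]), which.max(-V[, 1] + V[, 3]),
           which.min(V[, 2] + V[, 3]))
  cons <- constrain_rigid_body(mesh, nodes = alt)
  sol2 <- solve_elastic(mesh, constraints = cons)
  ref <- max(abs(base$stress_nodes))
  expect_lt(max(abs(sol2$stress_nodes - base$stress_nodes)) / ref, 1e-3)
})

test_that("quadratic elements out-converge linear ones on the thin-wall benchmark", {
  cfg <- model_config(n_septa = 0L, shell_thickness = 0.5)
  solid <- build_shell(cfg, mesh_options(n_theta = 48L, target_size = 3))
  f1 <- tet_mesh(solid, order = 1L)
  f2 <- tet_mesh(solid, order = 2L)
  s1 <- solve_elastic(f1)
  s2 <- solve_elastic(f2)
  e1 <- validation_error(s1, f1)
  e2 <- validation_error(s2, f2)
  expect_lt(e2, e1)
})
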