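test_that("the spacing rule reproduces the reference septa counts", {
  expect_equal(model_config(septal_spacing = 5)$n_septa, 5L)
  expect_equal(model_config(septal_spacing = 10)$n_septa, 3L)
  expect_equal(model_config(septal_spacing = 20)$n_septa, 2L)
  expect_equal(model_config(shell_thickness = 0.5)$outer_radius, 9.61)
  expect_equal(model_config(shell_thickness = 0.1)$outer_radius, 9.21)
  expect_error(model_config(septal_spacing = 0.3, septal_thickness = 0.4),
               "spacing")
})

test_that("a septa-free capped cylinder is watertight with the analytic volume", {
  cfg <- model_config(n_septa = 0L)
  solid <- build_shell(cfg, mesh_options(n_theta = 64L, target_size = 2))
  expect_true(is_watertight(solid$shell))
  fem <- tet_mesh(solid, order = 1L)
  va <- analytic_shell_volume(cfg)
  expect_equal(fem$quality$total_volume, va, tolerance = 0.01)
  # the divergence-theorem volume of the labelled boundary agrees exactly
  expect_equal(mesh_volume(solid$shell), fem$quality$total_volume,
               tolerance = 1e-9)
})

test_that("assembled septate models are conforming and labelled", {
  tm <- tiny_sexilobate()
  solid <- tm$solid
  fem <- tm$mesh
  expect_true(is_watertight(solid$shell))
  expect_equal(ncol(fem$tets), 10L)           # quadratic elements
  expect_equal(fem$quality$n_inverted, 0L)
  expect_gt(fem$quality$min_volume, 0)
  regions <- unique(fem$element_region)
  expect_setequal(regions, c("shell_wall", "cap_bottom", "cap_top",
                             paste0("septum_", 1:5)))
  # every septum shares nodes with the wall (conformal fusion)
  wall_nodes <- unique(as.vector(
    fem$tets[fem$element_region == "shell_wall", 1:4]))
  for (s in 1:5) {
    sn <- unique(as.vector(
      fem$tets[fem$element_region == sprintf("septum_%d", s), 1:4]))
    expect_gt(length(intersect(sn, wall_nodes)), 40L)
  }
  # external load surface is a closed 2-manifold
  expect_true(is_watertight(list(vertices = fem$nodes,
                                 triangles = fem$external[, 1:3])))
})

test_that("meshing is deterministic", {
  cfg <- model_config(n_septa = 2L, septal_spacing = 20)
  m1 <- tet_mesh(build_shell(cfg, mesh_options(n_theta = 48L, target_size = 3)))
  m2 <- tet_mesh(build_shell(cfg, mesh_options(n_theta = 48L, target_size = 3)))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
})

test_that("mesh writers emit valid plain-text files", {
  tm <- tiny_sexilobate()
  d <- tempfile(); dir.create(d)
  stl <- write_stl(list(vertices = tm$solid$shell$vertices,
                        triangles = tm$solid$shell$triangles[1:50, ]),
                   file.path(d, "shell.stl"))
  expect_true(any(grepl("facet normal", readLines(stl, n = 5))))
  vtk <- write_vtk(tm$mesh, file.path(d, "mesh.vtk"),
                   point_data = list(z = tm$mesh$nodes[, 3]))
  ln <- readLines(vtk, n = 6)
  expect_true(any(grepl("UNSTRUCTURED_GRID", ln)))
  msh <- write_msh(tm$mesh, file.path(d, "mesh.msh"))
  expect_true(any(grepl("MeshFormat", readLines(msh, n = 2))))
  unlink(d, recursive = TRUE)
})
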