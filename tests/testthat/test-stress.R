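test_that("thin-wall hoop theory matches the reference values", {
  expect_equal(hoop_stress_theory(2, 9.11, 0.5), 36.44)
  expect_equal(hoop_stress_theory(2, 9.11, 0.1), 182.2)
  expect_equal(hoop_stress_theory(0, 9.11, 0.5), 0)
  expect_error(hoop_stress_theory(2, 9.11, 0), "`t`")
})

test_that("cylindrical decomposition preserves tensor invariants", {
  P <- 3
  hydro <- diag(c(-P, -P, -P))
  out <- to_cylindrical(hydro, c(1, 2, 0.5))
  expect_equal(unlist(out), c(radial = -P, tangential = -P,
                              longitudinal = -P))
  axial <- matrix(0, 3, 3); axial[3, 3] <- 7
  out <- to_cylindrical(axial, c(2, 0, 1))
  expect_equal(out$longitudinal, 7)
  expect_equal(out$radial, 0)
  expect_equal(out$tangential, 0)
  # trace invariance on random symmetric tensors
  set.seed(42)
  S <- matrix(rnorm(60), 10, 6)
  pts <- matrix(rnorm(30), 10, 3); pts[, 1] <- pts[, 1] + 3
  cyl <- to_cylindrical(S, pts)
  expect_equal(cyl$radial + cyl$tangential + cyl$longitudinal,
               S[, 1] + S[, 2] + S[, 3], tolerance = 1e-12)
  expect_error(to_cylindrical(hydro, c(0, 0, 5)), "axis")
})

test_that("max principal stress equals the largest eigenvalue", {
  expect_equal(max_principal(diag(c(3, 2, 1))), 3)
  expect_equal(max_principal(diag(c(-2, -2, -2))), -2)
  shear <- matrix(0, 3, 3); shear[1, 2] <- shear[2, 1] <- 5
  expect_equal(max_principal(shear), 5, tolerance = 1e-12)
  expect_error(max_principal(matrix(1:9, 3, 3)), "symmetric")
  # vectorised path agrees with eigen() on random tensors
  set.seed(7)
  S <- matrix(rnorm(120), 20, 6)
  ref <- apply(S, 1, function(v) {
    A <- matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3)
    max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_equal(max_principal(S), ref, tolerance = 1e-10)
})

test_that("line probes are periodic and axisymmetric far from septa", {
  tm <- tiny_sexilobate()
  p1 <- line_probe(tm$solution, tm$mesh, theta = 0.3)
  p2 <- line_probe(tm$solution, tm$mesh, theta = 0.3 + 2 * pi)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$position_mm) > 0))
  expect_true(all(is.finite(p1$tangential_MPa)))
})

test_that("region statistics behave on uniform and model fields", {
  cs <- cube_solution()
  mp <- max_principal(cs$solution$stress_nodes)
  expect_equal(sd(mp), 0, tolerance = 1e-6)
  expect_equal(mean(mp), max(mp), tolerance = 1e-6)
  tm <- tiny_sexilobate()
  wall <- region_stats(tm$solution, tm$mesh, "shell_wall")
  sep <- region_stats(tm$solution, tm$mesh, "septum")
  expect_gte(wall$peak_MPa, wall$mean_MPa)
  expect_gte(sep$peak_MPa, sep$mean_MPa)
  expect_gte(wall$sd_MPa, 0)
  expect_gte(sep$n, 5)  # septum stats sample the top-decile contour zone
  # linear scaling of means with pressure
  s3 <- scale_solution(tm$solution, 3)
  wall3 <- region_stats(s3, tm$mesh, "shell_wall")
  expect_equal(wall3$mean_MPa, 1.5 * wall$mean_MPa, tolerance = 1e-10)
  expect_error(region_stats(tm$solution, tm$mesh, "septum_99"), "region")
})

test_that("septum centre displacement scales with pressure and needs septa", {
  tm <- tiny_sexilobate()
  d2 <- septum_centre_displacement(tm$solution, tm$mesh)
  expect_gt(d2, 0)
  d4 <- septum_centre_displacement(scale_solution(tm$solution, 4), tm$mesh)
  expect_equal(d4, 2 * d2, tolerance = 1e-10)
})

test_that("depth equivalence is exact for identical models", {
  tab <- data.frame(pressure = c(1, 2, 3), mean_MPa = c(10, 20, 30))
  out <- depth_equivalent(tab, tab, reference_pressure = 2)
  expect_equal(out$pressure, 2)
  expect_equal(out$extra_depth_m, 0)
  flat <- data.frame(pressure = c(1, 2, 3), mean_MPa = c(5, 5, 5))
  expect_error(depth_equivalent(tab, flat), "zero-slope")
  # ~100 m of seawater per MPa
  tab2 <- data.frame(pressure = c(1, 2, 3), mean_MPa = c(9, 18, 27))
  out <- depth_equivalent(tab, tab2, reference_pressure = 2)
  expect_equal(out$extra_depth_m / (out$pressure - 2), 1e6 / (1025 * 9.81))
})
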