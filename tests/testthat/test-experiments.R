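test_that("fixtures carry analytic truths", {
  expect_error(make_fixture("bogus"), "arg")
  fx <- make_fixture("hydrostatic_cube", pressure = 3)
  expect_equal(fx$truth[["xx"]], -3)
  fx <- make_fixture("capped_cylinder", t = 0.5,
                     mesh = mesh_options(n_theta = 48L, target_size = 3))
  expect_equal(fx$truth, 36.44)
  fx <- make_fixture("pressurized_sphere")
  expect_equal(fx$truth, -2 * 10 / (2 * 0.1))
})

test_that("the thin spherical shell carries the membrane stress", {
  fx <- make_fixture("pressurized_sphere", pressure = 2)
  sol <- solve_elastic(fx$mesh)
  # tangential (most negative principal) stress at element centroids
  st <- sol$stress_element
  minp <- -max_principal(-st)  # smallest eigenvalue via negation
  expect_equal(mean(minp), fx$truth, tolerance = 0.03)
})

test_that("the reference suite spans 11 distinct geometries", {
  suite <- reference_suite()
  expect_length(suite, 11L)
  sigs <- vapply(suite, function(s) {
    phragmoFEM:::config_signature(s$config,
                                  phragmoFEM:::resolve_mesh(s$config, s$mesh))
  }, "")
  expect_equal(length(unique(sigs)), 11L)
  # Koch models carry the 1/2/3 MPa pressure series
  expect_equal(suite$koch_i2$pressures, c(1, 2, 3))
  # spacing suite: 5/10/20 mm with 5/3/2 septa
  expect_equal(suite$sexilobate_s20$config$n_septa, 2L)
})

test_that("an empty suite runs to completion with empty results", {
  out <- run_suite(list(), out_dir = tempfile(), quiet = TRUE)
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0L)
})

test_that("suites are resumable and bit-deterministic", {
  suite <- list(tiny = list(
    config = model_config(n_septa = 2L, septal_spacing = 20,
                          suture = suture_spec("lobate", n_lobes = 3L)),
    mesh = mesh_options(n_theta = 48L, target_size = 3),
    pressures = 2))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_suite(suite, out_dir = d1, quiet = TRUE)
  r1b <- run_suite(suite, out_dir = d1, quiet = TRUE)  # cached
  r2 <- run_suite(suite, out_dir = d2, quiet = TRUE)   # fresh rebuild
  expect_identical(r1, r1b)
  # all numeric outputs are bit-identical; wall-clock columns are not
  drop_t <- function(d) d[setdiff(names(d), c("build_s", "solve_s"))]
  expect_identical(drop_t(r1), drop_t(r2))
  expect_true(file.exists(file.path(d1, "probe_tiny.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("model self-comparison is exactly zero percent", {
  tmp <- tempfile()
  suite <- list(a = list(
    config = model_config(n_septa = 2L, septal_spacing = 20,
                          suture = suture_spec("lobate", n_lobes = 3L)),
    mesh = mesh_options(n_theta = 48L, target_size = 3),
    pressures = 2))
  res <- run_suite(suite, out_dir = tmp, quiet = TRUE)
  cmp <- compare_models(res, "a", "a")
  expect_true(all(cmp$percent_change == 0))
  expect_error(compare_models(res, "a", "a", pressure = 9), "pressure")
  unlink(tmp, recursive = TRUE)
})
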