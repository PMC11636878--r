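# Relative L2 errors, wall shear stress, reference import and case-grid maps.

test_that("relative_l2 matches hand arithmetic and rejects a zero reference", {
  expect_equal(relative_l2(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(relative_l2(2 * c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(relative_l2(c(1, 2), c(1, 1)), 100 / sqrt(2))
  expect_error(relative_l2(c(1, 2), c(0, 0)), "identically zero")
})

test_that("relative_l2 is scale invariant and obeys the scaled triangle bound", {
  set.seed(11)
  for (i in 1:20) {
    pred <- rnorm(30); ref <- rnorm(30); mid <- rnorm(30)
    cc <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(relative_l2(cc * pred, cc * ref), relative_l2(pred, ref))
    lhs <- relative_l2(pred, ref)
    rhs <- relative_l2(pred, mid) * sqrt(sum(mid^2)) / sqrt(sum(ref^2)) +
      relative_l2(mid, ref)
    expect_lte(lhs, rhs + 1e-9)
  }
})

test_that("wall shear stress reproduces the Poiseuille closed form", {
  ctx <- tiny_ctx()
  field <- analytic_straight_channel(ctx)
  w <- model_wall_shear_stress(field, c(0.25, 0.5, 0.75), "bottom",
                               case_parameters(0, 0.134))
  # mu * u_max / R0 under the symmetric-tensor definition (half the
  # conventional 2 mu u_max / R0)
  expect_equal(w$wss, rep(1.85e-3 * 0.00925 / 0.05, 3), tolerance = 1e-12)
  expect_equal(w$wss, rep(3.4225e-4, 3), tolerance = 1e-6)
  w2 <- model_wall_shear_stress(field, 0.5, "top", case_parameters(0, 0.134),
                                convention = "conventional_2x")
  expect_equal(w2$wss, 2 * 3.4225e-4, tolerance = 1e-6)
})

test_that("strain-free fields carry zero wall shear stress", {
  n <- 10
  normals <- cbind(rep(0, n), rep(1, n))
  zerog <- matrix(0, n, 4)
  expect_equal(wall_shear_stress(zerog, normals, 1.85e-3), rep(0, n))
  # rigid-body rotation u = -wy, v = wx: ux = vy = 0, uy = -w, vx = w
  rot <- cbind(ux = 0, uy = rep(-2, n), vx = rep(2, n), vy = 0)
  expect_equal(wall_shear_stress(rot, normals, 1.85e-3), rep(0, n))
  expect_error(wall_shear_stress(rot, 2 * normals, 1.85e-3), "unit")
})

test_that("the analytic straight channel satisfies its boundary values", {
  ctx <- tiny_ctx()
  field <- analytic_straight_channel(ctx)
  s <- sample_flow_field(field, data.frame(x = c(1, 0, 0.5), y = c(0.02, 0, 0.05)))
  expect_equal(s$p[1], 0)                                   # outlet
  expect_equal(s$p[2], 2 * 1000 * 1.85e-6 * 0.00925 / 0.05^2)  # inlet, 0.013690
  expect_equal(s$p[2], 0.013690, tolerance = 1e-6)
  expect_equal(s$u[3], 0)                                   # wall no-slip
  expect_equal(s$u[2], 0.00925)                             # peak inlet velocity
})

test_that("reference fields round-trip through CSV and import validates columns", {
  ctx <- tiny_ctx()
  field <- analytic_straight_channel(ctx)
  g <- expand.grid(x = seq(0, 1, length.out = 12),
                   y = seq(-0.05, 0.05, length.out = 8))
  s <- sample_flow_field(field, g)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(s, path, row.names = FALSE)
  back <- import_reference(path)
  expect_equal(back$u, s$u)
  expect_equal(back$p, s$p)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1, y = 2, u = 3), bad, row.names = FALSE)
  expect_error(import_reference(bad), "missing: v, p")
})

test_that("legacy ASCII VTK point clouds are parsed", {
  path <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c(
    "# vtk DataFile Version 3.0", "flow sample", "ASCII",
    "DATASET POLYDATA", "POINTS 3 float",
    "0.0 0.01 0", "0.5 -0.02 0", "1.0 0.0 0",
    "POINT_DATA 3",
    "VECTORS velocity float",
    "0.001 0 0", "0.002 0.0001 0", "0.003 -0.0001 0",
    "SCALARS p float 1", "LOOKUP_TABLE default",
    "0.01 0.005 0.0"), path)
  ref <- import_reference(path)
  expect_equal(ref$x, c(0, 0.5, 1))
  expect_equal(ref$u, c(0.001, 0.002, 0.003))
  expect_equal(ref$v, c(0, 1e-4, -1e-4))
  expect_equal(ref$p, c(0.01, 0.005, 0))
})

test_that("interpolation is skipped on exact matches and accurate on fine grids", {
  ctx <- tiny_ctx()
  field <- analytic_straight_channel(ctx)
  fine <- expand.grid(x = seq(0, 1, length.out = 120),
                      y = seq(-0.05, 0.05, length.out = 60))
  ref <- sample_flow_field(field, fine)
  same <- interp_reference(ref, fine[c(5, 50, 500), ])
  expect_identical(attr(same, "interpolation"), "none (exact point match)")
  expect_equal(same$u, ref$u[c(5, 50, 500)])
  set.seed(12)
  coarse <- data.frame(x = runif(40, 0.1, 0.9), y = runif(40, -0.04, 0.04))
  it <- interp_reference(ref, coarse, method = "idw")
  truth <- sample_flow_field(field, coarse)
  expect_lt(max(abs(it$u - truth$u)), 1e-3 * ctx$u_max * 120)
  expect_match(attr(it, "interpolation"), "idw")
})

test_that("a model evaluated against itself has zero error everywhere", {
  ctx <- tiny_ctx()
  model <- init_model(tiny_spec("mixed"), ctx, seed = 4)
  er <- error_report(model, model, case_parameters(0.025, 0.13),
                     n = 200, n_wall = 30, seed = 3)
  expect_equal(er$epsilon_u, 0)
  expect_equal(er$epsilon_p, 0)
  expect_equal(er$epsilon_wss_mag, 0)
  expect_equal(er$N, 200)
})

test_that("case-grid error tables cover every case, skip missing references, and are seeded", {
  ctx <- tiny_ctx()
  model <- init_model(tiny_spec("mixed"), ctx, seed = 4)
  cases <- data.frame(A = c(0, 0.025, 0.035), sigma = c(0.134, 0.13, 0.1))
  ref_for <- function(cp) if (cp$A == 0) analytic_straight_channel(ctx) else NULL
  t1 <- case_grid_errors(model, cases, ref_for, n = 100, n_wall = 10, seed = 2)
  t2 <- case_grid_errors(model, cases, ref_for, n = 100, n_wall = 10, seed = 2)
  expect_equal(nrow(t1), 3L)
  expect_identical(t1, t2)
  expect_false(t1$skipped[1])
  expect_true(all(t1$skipped[2:3]))
  # self-reference gives zeros for all evaluated cases
  t3 <- case_grid_errors(model, cases, function(cp) model, n = 50,
                         n_wall = 10, seed = 2)
  expect_true(all(t3$eps_u == 0))
})
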