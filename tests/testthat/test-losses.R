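# Unit-normalized physics / boundary losses and the gPINN derivative loss.

test_that("the analytic straight-channel solution annihilates every loss term", {
  ctx <- tiny_ctx()
  field <- analytic_straight_channel(ctx)
  g0 <- channel_geometry(case_parameters(0, 0.134))
  cs <- sample_collocation(g0, c(200, 200, 200, 200, 1000), seed = 3)
  r <- pde_residuals(field, cs)
  expect_lt(max(abs(as.matrix(r))), 1e-10)
  lb <- pinn_losses(field, cs)
  expect_lt(lb$continuity + lb$momentum, 1e-10)
  expect_lt(lb$wall_noslip + lb$outlet_pressure + lb$inlet_u + lb$inlet_v, 1e-12)
})

test_that("a constant field has exactly zero PDE residuals", {
  ctx <- tiny_ctx()
  const_field <- flow_field(function(xt, yt, ss, ctx) {
    z <- tubepinn:::st_scale(xt, 0)
    list(u = z, v = z, p = tubepinn:::st_shift(z, 0.42))
  }, ctx)
  pts <- random_interior(50, seed = 6)
  r <- pde_residuals(const_field, pts, case_parameters(0.025, 0.13))
  expect_true(all(as.matrix(r) == 0))
})

test_that("normalization identities hold for single residuals and wall velocities", {
  norms <- normalization_constants()
  one_point <- data.frame(continuity = 1 / norms$V_s, momentum_x = 0, momentum_y = 0)
  expect_equal(physics_loss(one_point, norms), 1.0)
  mom_point <- data.frame(continuity = 0, momentum_x = norms$V_m / norms$V_s^2,
                          momentum_y = 0)
  expect_equal(physics_loss(mom_point, norms), 1.0)
  # model emitting u = V_m/V_s on walls -> wall term exactly 1
  ctx <- tiny_ctx()
  uconst <- flow_field(function(xt, yt, ss, ctx) {
    z <- tubepinn:::st_scale(xt, 0)
    list(u = tubepinn:::st_shift(z, ctx$norms$V_u), v = z, p = z)
  }, ctx)
  g <- channel_geometry(case_parameters(0.02, 0.12))
  cs <- sample_collocation(g, c(0, 0, 40, 40, 0), seed = 4)
  expect_equal(bc_loss(uconst, cs)$wall_noslip, 1.0)
})

test_that("zero model gives the closed-form inlet deficit of 8/15", {
  ctx <- tiny_ctx()
  zf <- zero_field(ctx)
  g0 <- channel_geometry(case_parameters(0, 0.134))
  cs <- sample_collocation(g0, c(200000, 10, 10, 10, 10), seed = 5)
  bl <- bc_loss(zf, cs)
  expect_equal(bl$inlet_u, 8 / 15, tolerance = 0.01)
  expect_equal(bl$wall_noslip, 0)
  expect_equal(bl$outlet_pressure, 0)
  expect_equal(bl$inlet_v, 0)
})

test_that("missing regions are reported absent, not zero", {
  ctx <- tiny_ctx()
  g0 <- channel_geometry(case_parameters(0, 0.134))
  cs <- sample_collocation(g0, c(10, 0, 10, 10, 0), seed = 6)
  bl <- bc_loss(zero_field(ctx), cs)
  expect_true(is.na(bl$outlet_pressure))
  expect_false(is.na(bl$inlet_u))
})

test_that("PDE residuals of a random network match central finite differences", {
  ctx <- tiny_ctx()
  case <- case_parameters(0.025, 0.13)
  fluid <- ctx$fluid
  for (seed in 1:5) {
    model <- init_model(tiny_spec("mixed"), ctx, seed = seed)
    pts <- random_interior(100, case, seed = 100 + seed)
    r <- pde_residuals(model, pts, case)
    f <- function(x, y) flow_eval(model, x, y, case,
                                  tubepinn:::ss_value())$states[[1L]]
    h <- 1e-4
    mid <- f(pts$x, pts$y)
    fx <- (f(pts$x + h, pts$y) - f(pts$x - h, pts$y)) / (2 * h)
    fy <- (f(pts$x, pts$y + h) - f(pts$x, pts$y - h)) / (2 * h)
    fxx <- (f(pts$x + h, pts$y) - 2 * mid + f(pts$x - h, pts$y)) / h^2
    fyy <- (f(pts$x, pts$y + h) - 2 * mid + f(pts$x, pts$y - h)) / h^2
    cont_fd <- fx[, 1] + fy[, 2]
    momx_fd <- mid[, 1] * fx[, 1] + mid[, 2] * fy[, 1] + fx[, 3] / fluid$rho -
      fluid$nu * (fxx[, 1] + fyy[, 1])
    momy_fd <- mid[, 1] * fx[, 2] + mid[, 2] * fy[, 2] + fy[, 3] / fluid$rho -
      fluid$nu * (fxx[, 2] + fyy[, 2])
    scale <- max(abs(cont_fd))
    expect_lt(max(abs(r$continuity - cont_fd)) / scale, 1e-4)
    scale_m <- max(abs(c(momx_fd, momy_fd)))
    expect_lt(max(abs(r$momentum_x - momx_fd)) / scale_m, 1e-4)
    expect_lt(max(abs(r$momentum_y - momy_fd)) / scale_m, 1e-4)
  }
})

test_that("gPINN derivative loss vanishes for a case-independent constant field", {
  ctx <- tiny_ctx()
  g <- channel_geometry(case_parameters(0.025, 0.13))
  cs <- sample_collocation(g, c(20, 20, 20, 20, 50), seed = 7)
  gl <- gpinn_loss(zero_field(ctx), cs)
  expect_equal(gl$total, 0)
})

test_that("gPINN derivative loss is nonnegative, finite, and matches finite differences", {
  ctx <- tiny_ctx()
  case <- list(A = 0.025, sigma = 0.13)
  g <- ctx_case_geom <- channel_geometry(case_parameters(case$A, case$sigma))
  cs <- sample_collocation(g, c(15, 15, 15, 15, 40), seed = 8)
  model <- init_model(tiny_spec("mixed"), ctx, seed = 23)
  gl <- gpinn_loss(model, cs)
  expect_true(is.finite(gl$total) && gl$total >= 0)
  # FD oracle: normalized residual derivative with respect to each case
  # parameter (wall points follow the wall)
  norms <- ctx$norms
  w <- tubepinn:::lambda_widths(ctx)
  intr <- cs$points[cs$points$region == "interior", ]
  h <- 1e-5
  for (lv in c("A", "sigma")) {
    shift_case <- function(d) {
      cc <- case; cc[[lv]] <- cc[[lv]] + d
      pde_residuals(model, data.frame(x = intr$x, y = intr$y),
                    suppressWarnings(case_parameters(cc$A, cc$sigma)))
    }
    up <- shift_case(h); dn <- shift_case(-h)
    dcont <- (up$continuity - dn$continuity) / (2 * h)
    dmomx <- (up$momentum_x - dn$momentum_x) / (2 * h)
    dmomy <- (up$momentum_y - dn$momentum_y) / (2 * h)
    fd_term <- w[[lv]]^2 * (norms$V_s^2 * mean(dcont^2) +
      mean(dmomx^2 + dmomy^2) / (norms$V_m / norms$V_s^2)^2)
    expect_equal(gl[[paste0("domain_", lv)]], fd_term, tolerance = 1e-3)
  }
})

test_that("losses grow quadratically in the perturbation amplitude", {
  ctx <- tiny_ctx()
  g0 <- channel_geometry(case_parameters(0, 0.134))
  cs <- sample_collocation(g0, c(100, 100, 100, 100, 400), seed = 9)
  eps <- 10^seq(-3, -1, length.out = 5)
  totals <- vapply(eps, function(e) {
    pinn_losses(perturbed_poiseuille(e, ctx), cs)$total
  }, 0)
  slope <- stats::coef(stats::lm(log(totals) ~ log(eps)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("loss terms are invariant under consistent unit rescaling", {
  set.seed(10)
  r <- data.frame(continuity = rnorm(20), momentum_x = rnorm(20),
                  momentum_y = rnorm(20))
  norms <- normalization_constants()
  # pre-normalized residuals with unit reference constants
  r_scaled <- data.frame(continuity = r$continuity * norms$V_s,
                         momentum_x = r$momentum_x / (norms$V_m / norms$V_s^2),
                         momentum_y = r$momentum_y / (norms$V_m / norms$V_s^2))
  expect_equal(physics_loss(r, norms),
               physics_loss(r_scaled, normalization_constants(1, 1, 1)))
})

test_that("total_loss is the weighted sum of its parts", {
  parts <- list(continuity = 0.1, momentum = 0.1, wall_noslip = 0.1,
                outlet_pressure = 0.1, inlet_u = 0.05, inlet_v = 0.05,
                derivative_terms = NULL)
  expect_equal(total_loss(parts, loss_weights(1, 1)), 0.5)
  parts$derivative_terms <- list(domain_A = 0.06, domain_sigma = 0.04)
  expect_equal(total_loss(parts, loss_weights(1, 1, 1)), 0.6)
  expect_equal(total_loss(parts, loss_weights(2, 1, 0.5)), 0.4 + 0.3 + 0.05)
})
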