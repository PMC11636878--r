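# ---------------------------------------------------------------------------
# Unit-normalized physics and boundary-condition losses, and the
# gradient-enhanced (gPINN) case-derivative loss.
#
# Continuity residuals are normalized by 1/V_s, momentum residuals by
# V_m / V_s^2, velocities by V_m / V_s and pressures by V_kg/(V_m V_s^2),
# so every loss term is dimensionless.  The derivative loss differentiates
# the already-normalized residuals with respect to the case parameters,
# each normalized by its trained range width.
# ---------------------------------------------------------------------------

#' Loss weights
#'
#' @param w_physics,w_bc,w_derivative nonnegative weights; the derivative
#'   weight is only active during a gPINN phase.
#' @return list of weights.
#' @export
loss_weights <- function(w_physics = 1, w_bc = 1, w_derivative = 1) {
  stopifnot(w_physics >= 0, w_bc >= 0, w_derivative >= 0)
  list(w_physics = w_physics, w_bc = w_bc, w_derivative = w_derivative)
}

# residual values (and lambda-derivatives when present) from an evaluated
# state bundle over ss
residuals_from_states <- function(states, ss, fluid, lam = FALSE) {
  g <- function(...) states[[ss_state_id(ss, c(...))]]
  u <- g()[, 1L]; v <- g()[, 2L]
  ux <- g("x")[, 1L]; vx <- g("x")[, 2L]; px <- g("x")[, 3L]
  uy <- g("y")[, 1L]; vy <- g("y")[, 2L]; py <- g("y")[, 3L]
  uxx <- g("x", "x")[, 1L]; vxx <- g("x", "x")[, 2L]
  uyy <- g("y", "y")[, 1L]; vyy <- g("y", "y")[, 2L]
  rho <- fluid$rho; nu <- fluid$nu
  out <- data.frame(
    continuity = ux + vy,
    momentum_x = u * ux + v * uy + px / rho - nu * (uxx + uyy),
    momentum_y = u * vx + v * vy + py / rho - nu * (vxx + vyy))
  if (lam) {
    for (lv in c("A", "sigma")) {
      uL <- g(lv)[, 1L]; vL <- g(lv)[, 2L]
      uxL <- g("x", lv)[, 1L]; vxL <- g("x", lv)[, 2L]; pxL <- g("x", lv)[, 3L]
      uyL <- g("y", lv)[, 1L]; vyL <- g("y", lv)[, 2L]; pyL <- g("y", lv)[, 3L]
      uxxL <- g("x", "x", lv)[, 1L]; vxxL <- g("x", "x", lv)[, 2L]
      uyyL <- g("y", "y", lv)[, 1L]; vyyL <- g("y", "y", lv)[, 2L]
      out[[paste0("continuity_d", lv)]] <- uxL + vyL
      out[[paste0("momentum_x_d", lv)]] <-
        uL * ux + u * uxL + vL * uy + v * uyL + pxL / rho - nu * (uxxL + uyyL)
      out[[paste0("momentum_y_d", lv)]] <-
        uL * vx + u * vxL + vL * vy + v * vyL + pyL / rho - nu * (vxxL + vyyL)
    }
  }
  out
}

# pull interior points (x, y, A, sigma) out of a collocation_set or df
interior_points <- function(points, case = NULL) {
  if (inherits(points, "collocation_set")) {
    df <- points$points[points$points$region == "interior", , drop = FALSE]
    data.frame(x = df$x, y = df$y, A = df$case_A, sigma = df$case_sigma)
  } else {
    df <- as.data.frame(points)
    if (!all(c("A", "sigma") %in% names(df))) {
      if (is.null(case)) stop("points lack case columns; supply `case`")
      cs <- expand_case(case, nrow(df))
      df$A <- cs$A; df$sigma <- cs$sigma
    }
    df[, c("x", "y", "A", "sigma")]
  }
}

#' Pointwise PDE residuals
#'
#' Continuity and momentum residuals of the steady incompressible
#' Navier-Stokes equations, with every derivative computed exactly
#' (including the analytic dependence of the TSC inputs on the
#' coordinates).
#'
#' @param model a `pinn_model` or analytic [flow_field()].
#' @param points a `collocation_set` (its interior region is used) or
#'   data.frame with `x`, `y` (and optionally `A`, `sigma`).
#' @param case case parameters when `points` has no case columns.
#' @return data.frame with per-point `continuity` (1/s), `momentum_x`,
#'   `momentum_y` (m/s^2).
#' @export
#' @examples
#' f <- analytic_straight_channel()
#' r <- pde_residuals(f, data.frame(x = 0.5, y = 0.01), case_parameters(0, 0.134))
#' max(abs(unlist(r)))  # exact solution: ~0
pde_residuals <- function(model, points, case = NULL) {
  pts <- interior_points(points, case)
  ctx <- if (inherits(model, "pinn_model")) model$ctx else model$ctx
  ev <- flow_eval(model, pts$x, pts$y, data.frame(A = pts$A, sigma = pts$sigma),
                  ss_phys())
  res <- residuals_from_states(ev$states, ss_phys(), ctx$fluid)
  if (any(!is.finite(as.matrix(res)))) {
    bad <- which(!stats::complete.cases(res) |
                 !is.finite(rowSums(as.matrix(res))))[1L]
    stop(sprintf("non-finite PDE residual at point (%.6g, %.6g)",
                 pts$x[bad], pts$y[bad]))
  }
  res
}

#' Unit-normalized physics loss
#'
#' Mean squared continuity residual divided by (1/V_s)^2 plus mean squared
#' momentum residual vector magnitude divided by (V_m/V_s^2)^2.
#'
#' @param residuals data.frame from [pde_residuals()].
#' @param norms a [normalization_constants()] list.
#' @return nonnegative dimensionless scalar.
#' @export
physics_loss <- function(residuals, norms = normalization_constants()) {
  stopifnot(nrow(residuals) >= 1L)
  c_cont <- norms$V_s^2
  c_mom <- 1 / (norms$V_m / norms$V_s^2)^2
  c_cont * mean(residuals$continuity^2) +
    c_mom * mean(residuals$momentum_x^2 + residuals$momentum_y^2)
}

# parabolic inlet target; the inlet half-width is R0 (the narrowing
# amplitude at x = 0 is A*exp(-x_center^2/(2 sigma^2)) <= 1e-3 * A over the
# trained ranges, so the inlet radius is treated as case-independent)
inlet_target <- function(y, A, sigma, ctx) {
  ctx$u_max * (1 - y^2 / ctx$R0^2)
}

#' Boundary-condition losses
#'
#' Four mean-squared, unit-normalized terms: no-slip wall velocity, outlet
#' pressure, inlet axial-velocity deficit against the parabolic profile, and
#' inlet transverse velocity.  Each term is averaged over its own point
#' count; the wall term pools top and bottom walls.  Regions absent from
#' `points` are reported as `NA` (absent), not zero.
#'
#' @param model a `pinn_model` or [flow_field()].
#' @param points a `collocation_set` or data.frame with `x, y, region` (and
#'   case columns or `case`).
#' @param case case parameters when `points` lacks case columns.
#' @param norms a [normalization_constants()] list.
#' @return named list `wall_noslip`, `outlet_pressure`, `inlet_u`, `inlet_v`.
#' @export
bc_loss <- function(model, points, case = NULL,
                    norms = normalization_constants()) {
  df <- if (inherits(points, "collocation_set")) points$points else as.data.frame(points)
  if (!all(c("case_A", "case_sigma") %in% names(df))) {
    cs <- expand_case(case, nrow(df))
    df$case_A <- cs$A; df$case_sigma <- cs$sigma
  }
  ctx <- model$ctx
  ev_vals <- function(sub) {
    ev <- flow_eval(model, sub$x, sub$y,
                    data.frame(A = sub$case_A, sigma = sub$case_sigma),
                    ss_value())
    ev$states[[1L]]
  }
  out <- list(wall_noslip = NA_real_, outlet_pressure = NA_real_,
              inlet_u = NA_real_, inlet_v = NA_real_)
  wall <- df[df$region %in% c("wall_top", "wall_bottom"), , drop = FALSE]
  if (nrow(wall)) {
    Y <- ev_vals(wall)
    out$wall_noslip <- mean(Y[, 1L]^2 + Y[, 2L]^2) / ctx$norms$V_u^2
  }
  outlet <- df[df$region == "outlet", , drop = FALSE]
  if (nrow(outlet)) {
    Y <- ev_vals(outlet)
    out$outlet_pressure <- mean(Y[, 3L]^2) / ctx$norms$V_p^2
  }
  inlet <- df[df$region == "inlet", , drop = FALSE]
  if (nrow(inlet)) {
    Y <- ev_vals(inlet)
    tgt <- inlet_target(inlet$y, inlet$case_A, inlet$case_sigma, ctx)
    out$inlet_u <- mean((Y[, 1L] - tgt)^2) / ctx$norms$V_u^2
    out$inlet_v <- mean(Y[, 2L]^2) / ctx$norms$V_u^2
  }
  out
}

# lambda normalization widths (the derivative loss differentiates with
# respect to lambda scaled by its trained range width)
lambda_widths <- function(ctx) {
  c(A = diff(ctx$A_range), sigma = diff(ctx$sigma_range))
}

#' Gradient-enhanced (gPINN) derivative loss
#'
#' Mean squared derivative of the unit-normalized governing-equation
#' residuals with respect to each (range-normalized) case parameter over the
#' interior, plus the same for the boundary-condition residuals over all
#' boundary regions.  Wall points follow the wall (y = +/-R(x; lambda)) under
#' case differentiation, and the TSC inputs are differentiated through their
#' analytic dependence on (A, sigma).
#'
#' @param model a `pinn_model` or [flow_field()].
#' @param points a `collocation_set` or data.frame with regions.
#' @param case case parameters when `points` lacks case columns.
#' @param norms a [normalization_constants()] list.
#' @return list with per-component terms (`domain_A`, `domain_sigma`,
#'   `boundary_A`, `boundary_sigma`) and their sum `total`.
#' @export
gpinn_loss <- function(model, points, case = NULL,
                       norms = normalization_constants()) {
  df <- if (inherits(points, "collocation_set")) points$points else as.data.frame(points)
  if (!all(c("case_A", "case_sigma") %in% names(df))) {
    cs <- expand_case(case, nrow(df))
    df$case_A <- cs$A; df$case_sigma <- cs$sigma
  }
  ctx <- model$ctx
  w <- lambda_widths(ctx)
  out <- list(domain_A = 0, domain_sigma = 0, boundary_A = 0, boundary_sigma = 0)
  intr <- df[df$region == "interior", , drop = FALSE]
  if (nrow(intr)) {
    ss <- ss_gpinn()
    ev <- flow_eval(model, intr$x, intr$y,
                    data.frame(A = intr$case_A, sigma = intr$case_sigma), ss)
    res <- residuals_from_states(ev$states, ss, ctx$fluid, lam = TRUE)
    if (any(!is.finite(as.matrix(res)))) stop("non-finite gPINN domain derivative")
    c_cont <- norms$V_s^2
    c_mom <- 1 / (norms$V_m / norms$V_s^2)^2
    for (lv in c("A", "sigma")) {
      out[[paste0("domain_", lv)]] <- w[[lv]]^2 *
        (c_cont * mean(res[[paste0("continuity_d", lv)]]^2) +
         c_mom * mean(res[[paste0("momentum_x_d", lv)]]^2 +
                      res[[paste0("momentum_y_d", lv)]]^2))
    }
  }
  # boundary terms: first lambda-derivatives of the normalized BC residuals
  ssb <- ss_bc_gpinn()
  bc_term <- function(sub, wall_side, resid_fun) {
    if (!nrow(sub)) return(NULL)
    ev <- flow_eval(model, sub$x, sub$y,
                    data.frame(A = sub$case_A, sigma = sub$case_sigma), ssb,
                    wall_side = wall_side)
    resid_fun(ev$states, sub)
  }
  acc <- list(A = list(), sigma = list())
  wall <- df[df$region %in% c("wall_top", "wall_bottom"), , drop = FALSE]
  if (nrow(wall)) {
    side <- ifelse(wall$region == "wall_top", 1, -1)
    for (lv in c("A", "sigma")) {
      d <- bc_term(wall, side, function(st, sub) {
        dl <- st[[ss_state_id(ssb, lv)]]
        (dl[, 1L]^2 + dl[, 2L]^2) / ctx$norms$V_u^2
      })
      acc[[lv]]$wall <- mean(d) * w[[lv]]^2
    }
  }
  outlet <- df[df$region == "outlet", , drop = FALSE]
  if (nrow(outlet)) {
    for (lv in c("A", "sigma")) {
      d <- bc_term(outlet, NULL, function(st, sub) {
        st[[ss_state_id(ssb, lv)]][, 3L]^2 / ctx$norms$V_p^2
      })
      acc[[lv]]$outlet <- mean(d) * w[[lv]]^2
    }
  }
  inlet <- df[df$region == "inlet", , drop = FALSE]
  if (nrow(inlet)) {
    for (lv in c("A", "sigma")) {
      d <- bc_term(inlet, NULL, function(st, sub) {
        dl <- st[[ss_state_id(ssb, lv)]]
        # the parabolic target is case-independent (inlet half-width R0)
        (dl[, 1L]^2 + dl[, 2L]^2) / ctx$norms$V_u^2
      })
      acc[[lv]]$inlet <- mean(d) * w[[lv]]^2
    }
  }
  for (lv in c("A", "sigma")) {
    out[[paste0("boundary_", lv)]] <- sum(unlist(acc[[lv]]))
  }
  out$total <- out$domain_A + out$domain_sigma + out$boundary_A + out$boundary_sigma
  if (!is.finite(out$total)) stop("non-finite gPINN derivative loss")
  out
}

#' Weighted total loss
#'
#' @param parts a `loss_breakdown` (or list with the same fields).
#' @param weights a [loss_weights()] list.
#' @return scalar total.
#' @export
total_loss <- function(parts, weights = loss_weights()) {
  bsum <- function(x) sum(unlist(x)[is.finite(unlist(x))])
  phys <- bsum(parts[c("continuity", "momentum")])
  bc <- bsum(parts[c("wall_noslip", "outlet_pressure", "inlet_u", "inlet_v")])
  deriv <- if (!is.null(parts$derivative_terms)) bsum(parts$derivative_terms) else 0
  weights$w_physics * phys + weights$w_bc * bc +
    (if (!is.null(parts$derivative_terms)) weights$w_derivative * deriv else 0)
}

#' Full loss breakdown for a collocation set
#'
#' @param model a `pinn_model` or [flow_field()].
#' @param points a `collocation_set` (all regions used).
#' @param weights a [loss_weights()] list.
#' @param gpinn include the gPINN derivative terms.
#' @param case case parameters when `points` lacks case columns.
#' @return object of class `loss_breakdown` with fields `continuity`,
#'   `momentum`, `wall_noslip`, `outlet_pressure`, `inlet_u`, `inlet_v`,
#'   `derivative_terms` (or NULL) and `total`.
#' @export
#' @examples
#' g <- channel_geometry(case_parameters(0, 0.134))
#' cs <- sample_collocation(g, c(50, 50, 50, 50, 200), seed = 1)
#' pinn_losses(analytic_straight_channel(), cs)$total  # exact solution: ~0
pinn_losses <- function(model, points, weights = loss_weights(),
                        gpinn = FALSE, case = NULL) {
  ctx <- model$ctx
  norms <- ctx$norms
  df <- if (inherits(points, "collocation_set")) points$points else as.data.frame(points)
  if (!all(c("case_A", "case_sigma") %in% names(df))) {
    cs <- expand_case(case, nrow(df))
    df$case_A <- cs$A; df$case_sigma <- cs$sigma
  }
  intr <- df[df$region == "interior", , drop = FALSE]
  cont <- mom <- NA_real_
  if (nrow(intr)) {
    res <- pde_residuals(model, data.frame(x = intr$x, y = intr$y,
                                           A = intr$case_A, sigma = intr$case_sigma))
    cont <- norms$V_s^2 * mean(res$continuity^2)
    mom <- mean(res$momentum_x^2 + res$momentum_y^2) / (norms$V_m / norms$V_s^2)^2
  }
  bc <- bc_loss(model, df, norms = norms)
  deriv <- NULL
  if (gpinn) {
    gl <- gpinn_loss(model, df, norms = norms)
    deriv <- gl[c("domain_A", "domain_sigma", "boundary_A", "boundary_sigma")]
  }
  parts <- structure(list(continuity = cont, momentum = mom,
                          wall_noslip = bc$wall_noslip,
                          outlet_pressure = bc$outlet_pressure,
                          inlet_u = bc$inlet_u, inlet_v = bc$inlet_v,
                          derivative_terms = deriv),
                     class = "loss_breakdown")
  parts$total <- total_loss(parts, weights)
  parts
}

#' @export
print.loss_breakdown <- function(x, ...) {
  flds <- c("continuity", "momentum", "wall_noslip", "outlet_pressure",
            "inlet_u", "inlet_v")
  for (f in flds) cat(sprintf("  %-16s %.6e\n", f, x[[f]]))
  if (!is.null(x$derivative_terms)) {
    cat(sprintf("  %-16s %.6e\n", "derivative",
                sum(unlist(x$derivative_terms))))
  }
  cat(sprintf("  %-16s %.6e\n", "total", x$total))
  invisible(x)
}
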