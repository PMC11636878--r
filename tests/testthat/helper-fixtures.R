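# Shared fixtures: tiny architectures, contexts and analytic fields.

tiny_ctx <- function() pinn_context()

tiny_spec <- function(kind = "mixed", widths = c(6L, 6L), use_tsc = TRUE) {
  switch(kind,
    mixed = network_spec("mixed", widths, use_tsc = use_tsc,
                         include_case = TRUE),
    mixed_single = network_spec("mixed", widths, use_tsc = use_tsc,
                                include_case = FALSE),
    hypernetwork = network_spec("hypernetwork", widths,
                                hyper_widths = c(5L, 5L), use_tsc = use_tsc,
                                hyper_feature = 4L),
    modes = network_spec("modes", widths, hyper_widths = c(5L, 5L),
                         use_tsc = use_tsc, n_modes = 4L, hyper_feature = 4L))
}

# random interior points of a case, away from the boundary
random_interior <- function(n, case = case_parameters(0.025, 0.13), seed = 1) {
  set.seed(seed)
  ctx <- tiny_ctx()
  geom <- channel_geometry(case, R0 = ctx$R0, x_center = ctx$x_center,
                           length = ctx$length)
  x <- runif(n, 0.02, ctx$length - 0.02)
  y <- runif(n, -0.9, 0.9) * radius_profile(x, geom)
  data.frame(x = x, y = y)
}

# constant-zero field (all outputs and derivatives vanish)
zero_field <- function(ctx = tiny_ctx()) {
  flow_field(function(xt, yt, ss, ctx) {
    z <- tubepinn:::st_scale(xt, 0)
    list(u = z, v = z, p = z)
  }, ctx = ctx)
}

# analytic straight-channel solution plus an O(eps) smooth perturbation
perturbed_poiseuille <- function(eps, ctx = tiny_ctx()) {
  flow_field(function(xt, yt, ss, ctx) {
    st_mul <- tubepinn:::st_mul; st_scale <- tubepinn:::st_scale
    st_add <- tubepinn:::st_add; st_sub <- tubepinn:::st_sub
    st_shift <- tubepinn:::st_shift; st_const <- tubepinn:::st_const
    R0 <- ctx$R0
    u0 <- st_scale(st_sub(st_const(1, ss),
                          st_scale(st_mul(yt, yt, ss), 1 / R0^2)), ctx$u_max)
    pg <- 2 * ctx$fluid$rho * ctx$fluid$nu * ctx$u_max / R0^2
    p0 <- st_scale(st_shift(st_scale(xt, -1), ctx$length), pg)
    yn <- st_scale(yt, 1 / R0)
    # polynomial bump: x^2 * y_n for u, x * y_n^2 for v, x^2 for p
    x2 <- st_mul(xt, xt, ss)
    bump_u <- st_scale(st_mul(x2, yn, ss), eps * ctx$u_max)
    bump_v <- st_scale(st_mul(xt, st_mul(yn, yn, ss), ss), eps * ctx$u_max)
    bump_p <- st_scale(x2, eps * ctx$norms$V_p)
    list(u = st_add(u0, bump_u), v = bump_v, p = st_add(p0, bump_p))
  }, ctx = ctx)
}

# plain single-network model equivalent to a hypernetwork at frozen lambda
frozen_lambda_fcnn <- function(hmodel, case) {
  spec <- hmodel$spec
  ss0 <- tubepinn:::ss_value()
  Xh <- tubepinn:::hyper_feature_states(case$A, case$sigma, hmodel$ctx, ss0)
  th <- tubepinn:::mlp_forward_states(hmodel$params$hyper, Xh, ss0)$out[[1L]][1L, ]
  spec_m <- network_spec("mixed", spec$main_widths, use_tsc = spec$use_tsc,
                         include_case = FALSE, input_bias = spec$input_bias)
  m <- init_model(spec_m, hmodel$ctx, seed = 1L)
  m$params$main <- tubepinn:::mlp_unflatten(hmodel$params$main_proto, th)
  m
}
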