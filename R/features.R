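# ---------------------------------------------------------------------------
# Network input features with exact derivative states.
#
# Inputs are dimensionless: x_n = 2x/length - 1 (identical to the TSC
# centerline distance), y_n = y/R0, the eight TSC, and for the mixed kind
# the range-normalized case parameters.  All derivative states (with respect
# to x, y and, when requested, A and sigma) are propagated analytically
# through the half-width profile R(x; A, sigma).
# ---------------------------------------------------------------------------

# half-width R as a state bundle; xt/At/sigt are state bundles (N-vectors)
radius_states <- function(xt, At, sigt, ctx, ss) {
  dx <- st_shift(xt, -ctx$x_center)
  dx2 <- st_mul(dx, dx, ss)
  denom <- st_scale(st_mul(sigt, sigt, ss), 2)
  expo <- st_exp(st_scale(st_div(dx2, denom, ss), -1), ss)
  st_sub(st_const(ctx$R0, ss), st_mul(At, expo, ss))
}

# Build the feature bundle for the main network.
#   x, y, A, sigma: N-vectors (A/sigma recycled per point)
#   wall_side: NULL, or +1/-1 per point (0 = free): points with side s != 0
#     follow the wall, y = s * R(x), so their lambda-derivatives include the
#     wall motion.
# Returns list(X = state bundle of N x n_features matrices, extras)
feature_states <- function(x, y, A, sigma, ctx, spec, ss, wall_side = NULL) {
  n <- length(x)
  A <- rep_len(A, n); sigma <- rep_len(sigma, n)
  has_A <- !is.na(ss_var_id(ss, "A"))
  has_s <- !is.na(ss_var_id(ss, "sigma"))
  xt <- st_var(x, "x", ss)
  At <- if (has_A) st_var(A, "A", ss) else st_const(A, ss)
  sigt <- if (has_s) st_var(sigma, "sigma", ss) else st_const(sigma, ss)
  Rt <- radius_states(xt, At, sigt, ctx, ss)
  yt <- st_var(y, "y", ss)
  if (!is.null(wall_side)) {
    side <- rep_len(wall_side, n)
    if (any(side != 0)) {
      yw <- st_mul(st_const(side, ss), Rt, ss)
      sel <- side != 0
      for (i in seq_along(yt)) {
        v <- yt[[i]]; v[sel] <- yw[[i]][sel]; yt[[i]] <- v
      }
    }
  }
  one <- st_const(rep(1, n), ss)
  cc <- st_shift(st_scale(xt, 2 / ctx$length), -1)
  yn <- st_scale(yt, 1 / ctx$R0)
  feats <- list(x_n = cc, y_n = yn)
  if (spec$use_tsc) {
    Ln <- st_div(yt, Rt, ss)
    dsq <- st_sub(one, st_mul(Ln, Ln, ss))
    feats <- c(feats, list(
      c = cc,
      L_n = Ln,
      d_sq = dsq,
      c_sq = st_mul(cc, cc, ss),
      L_n_sq = st_mul(Ln, Ln, ss),
      c_dsq = st_mul(cc, dsq, ss),
      c_Ln = st_mul(cc, Ln, ss),
      Ln_dsq = st_mul(Ln, dsq, ss)))
  }
  if (spec$include_case) {
    feats <- c(feats, lambda_feature_list(At, sigt, ctx, ss))
  }
  feats <- feats[spec$input_names]
  X <- lapply(seq_len(ss$n_states), function(si) {
    do.call(cbind, lapply(feats, function(f) f[[si]]))
  })
  list(X = X, R = Rt)
}

# range-normalized case parameters as state bundles
lambda_feature_list <- function(At, sigt, ctx, ss) {
  Aw <- diff(ctx$A_range) / 2; Am <- mean(ctx$A_range)
  Sw <- diff(ctx$sigma_range) / 2; Sm <- mean(ctx$sigma_range)
  list(A_n = st_shift(st_scale(At, 1 / Aw), -Am / Aw),
       sigma_n = st_shift(st_scale(sigt, 1 / Sw), -Sm / Sw))
}

# feature bundle for the side network f_h (inputs: normalized lambda)
hyper_feature_states <- function(A, sigma, ctx, ss) {
  has_A <- !is.na(ss_var_id(ss, "A"))
  has_s <- !is.na(ss_var_id(ss, "sigma"))
  At <- if (has_A) st_var(A, "A", ss) else st_const(A, ss)
  sigt <- if (has_s) st_var(sigma, "sigma", ss) else st_const(sigma, ss)
  feats <- lambda_feature_list(At, sigt, ctx, ss)
  lapply(seq_len(ss$n_states), function(si) {
    cbind(feats$A_n[[si]], feats$sigma_n[[si]])
  })
}
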