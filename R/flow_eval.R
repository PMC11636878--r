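# ---------------------------------------------------------------------------
# Evaluating flow fields (PINN models and analytic references) together with
# their derivative states, and the reverse pass from output adjoints to
# trainable-parameter gradients.
# ---------------------------------------------------------------------------

# normalize a "case" argument to per-point A / sigma vectors
expand_case <- function(case, n) {
  if (inherits(case, "case_parameters")) {
    list(A = rep(case$A, n), sigma = rep(case$sigma, n))
  } else if (is.data.frame(case)) {
    stopifnot(all(c("A", "sigma") %in% names(case)))
    list(A = rep_len(case$A, n), sigma = rep_len(case$sigma, n))
  } else if (is.list(case)) {
    list(A = rep_len(case$A, n), sigma = rep_len(case$sigma, n))
  } else stop("case must be case_parameters, list or data.frame with A, sigma")
}

output_scales <- function(ctx) c(ctx$norms$V_u, ctx$norms$V_u, ctx$norms$V_p)

st_col_scale <- function(states, scales) {
  lapply(states, function(m) sweep(m, 2L, scales, "*"))
}

#' Evaluate a flow field and its derivative states
#'
#' Generic over PINN models and analytic reference fields.  Returns the
#' (u, v, p) values in SI units together with every derivative state of the
#' requested `state_set` (first/second/third derivatives with respect to
#' coordinates and case parameters).
#'
#' @param object a `pinn_model` or `flow_field`.
#' @param x,y point coordinates (m).
#' @param case a [case_parameters()] object or data.frame with per-point
#'   `A`, `sigma`.
#' @param ss a `state_set` (internal); defaults to value-only.
#' @param wall_side optional per-point -1/0/+1: nonzero entries follow the
#'   wall y = side * R(x) when differentiating with respect to the case
#'   parameters.
#' @param keep_cache keep the forward cache (needed for gradients).
#' @return list with `states` (list of N x 3 matrices, columns u, v, p) and
#'   optionally `cache`.
#' @export
flow_eval <- function(object, x, y, case, ss = ss_value(),
                      wall_side = NULL, keep_cache = FALSE) {
  UseMethod("flow_eval")
}

#' @export
flow_eval.pinn_model <- function(object, x, y, case, ss = ss_value(),
                                 wall_side = NULL, keep_cache = FALSE) {
  model <- object
  n <- length(x)
  cs <- expand_case(case, n)
  ctx <- model$ctx
  spec <- model$spec
  scales <- output_scales(ctx)
  fs <- feature_states(x, y, cs$A, cs$sigma, ctx, spec, ss, wall_side)
  lam_vids <- c(A = ss_var_id(ss, "A"), sigma = ss_var_id(ss, "sigma"))
  lam_vids <- lam_vids[!is.na(lam_vids)]

  if (spec$kind == "mixed") {
    fw <- mlp_forward_states(model$params$main, fs$X, ss, keep_cache = keep_cache)
    states <- st_col_scale(fw$out, scales)
    cache <- if (keep_cache) list(kind = "mixed", fw = fw$cache, n = n) else NULL
  } else if (spec$kind == "modes") {
    fwq <- mlp_forward_states(model$params$main, fs$X, ss, keep_cache = keep_cache)
    Xh <- hyper_feature_states(cs$A, cs$sigma, ctx, ss)
    fwh <- mlp_forward_states(model$params$hyper, Xh, ss, keep_cache = keep_cache)
    B <- spec$n_modes
    states <- vector("list", ss$n_states)
    for (ai in seq_len(ss$n_states)) {
      plan <- ss$mul_plan[[ai]]
      out <- matrix(0, n, 3L)
      for (i in 1:3) {
        colsel <- ((i - 1L) * B + 1L):(i * B)
        acc <- 0
        for (r in seq_len(nrow(plan))) {
          term <- rowSums(fwq$out[[plan$bi[r]]] * fwh$out[[plan$gi[r]]][, colsel, drop = FALSE])
          acc <- acc + if (plan$mult[r] == 1L) term else plan$mult[r] * term
        }
        out[, i] <- acc
      }
      states[[ai]] <- out
    }
    states <- st_col_scale(states, scales)
    cache <- if (keep_cache) {
      list(kind = "modes", fwq = fwq, fwh = fwh, n = n)
    } else NULL
  } else { # hypernetwork
    key <- paste(cs$A, cs$sigma)
    uc <- !duplicated(key)
    ucase <- data.frame(A = cs$A[uc], sigma = cs$sigma[uc])
    gidx <- match(key, key[uc])
    Xh <- hyper_feature_states(ucase$A, ucase$sigma, ctx, ss)
    fwh <- mlp_forward_states(model$params$hyper, Xh, ss, keep_cache = keep_cache)
    proto <- model$params$main_proto
    states <- vector("list", ss$n_states)
    for (ai in seq_len(ss$n_states)) states[[ai]] <- matrix(0, n, 3L)
    case_caches <- vector("list", nrow(ucase))
    case_params <- vector("list", nrow(ucase))
    case_wt <- vector("list", nrow(ucase))
    for (ci in seq_len(nrow(ucase))) {
      sel <- which(gidx == ci)
      pm <- mlp_unflatten(proto, fwh$out[[1L]][ci, ])
      wt <- NULL
      if (length(lam_vids)) {
        wt <- lapply(seq_along(pm$W), function(l) list(W = list(), b = list()))
        for (v in seq_along(lam_vids)) {
          vid <- lam_vids[[v]]
          tang <- mlp_unflatten(proto, fwh$out[[vid]][ci, ])
          for (l in seq_along(pm$W)) {
            wt[[l]]$W[[as.character(vid)]] <- tang$W[[l]]
            if (!is.null(tang$b[[l]])) wt[[l]]$b[[as.character(vid)]] <- tang$b[[l]]
          }
        }
      }
      Xc <- lapply(fs$X, function(m) m[sel, , drop = FALSE])
      fwc <- mlp_forward_states(pm, Xc, ss, wt = wt, keep_cache = keep_cache)
      for (ai in seq_len(ss$n_states)) states[[ai]][sel, ] <- fwc$out[[ai]]
      case_caches[[ci]] <- fwc$cache
      case_params[[ci]] <- pm
      case_wt[[ci]] <- wt
    }
    states <- st_col_scale(states, scales)
    cache <- if (keep_cache) {
      list(kind = "hypernetwork", fwh = fwh, gidx = gidx, ucase = ucase,
           case_caches = case_caches, case_params = case_params,
           case_wt = case_wt, n = n)
    } else NULL
  }
  list(states = states, cache = cache)
}

# reverse pass: adjoints on the SI-scaled output states -> flattened gradient
# over the trainable parameters (same layout as model_flatten)
pinn_grad <- function(model, cache, out_adj, ss) {
  scales <- output_scales(model$ctx)
  adj <- lapply(out_adj, function(m) {
    if (is.null(m)) NULL else sweep(m, 2L, scales, "*")
  })
  spec <- model$spec
  if (cache$kind == "mixed") {
    rv <- mlp_reverse_states(model$params$main, cache$fw, adj, ss)
    return(mlp_grad_flatten(model$params$main, rv))
  }
  if (cache$kind == "modes") {
    B <- spec$n_modes
    fwq <- cache$fwq; fwh <- cache$fwh
    n <- cache$n
    q_adj <- vector("list", ss$n_states)
    M_adj <- vector("list", ss$n_states)
    addm <- function(lst, i, val) {
      if (is.null(lst[[i]])) lst[[i]] <- val else lst[[i]] <- lst[[i]] + val
      lst
    }
    for (ai in seq_len(ss$n_states)) {
      ya <- adj[[ai]]
      if (is.null(ya)) next
      plan <- ss$mul_plan[[ai]]
      for (i in 1:3) {
        colsel <- ((i - 1L) * B + 1L):(i * B)
        yai <- ya[, i]
        for (r in seq_len(nrow(plan))) {
          m <- if (plan$mult[r] == 1L) yai else yai * plan$mult[r]
          q_adj <- addm(q_adj, plan$bi[r],
                        fwh$out[[plan$gi[r]]][, colsel, drop = FALSE] * m)
          Mc <- fwq$out[[plan$bi[r]]] * m
          if (is.null(M_adj[[plan$gi[r]]])) {
            M_adj[[plan$gi[r]]] <- matrix(0, n, 3L * B)
          }
          M_adj[[plan$gi[r]]][, colsel] <- M_adj[[plan$gi[r]]][, colsel] + Mc
        }
      }
    }
    rvq <- mlp_reverse_states(model$params$main, fwq$cache, q_adj, ss)
    rvh <- mlp_reverse_states(model$params$hyper, fwh$cache, M_adj, ss)
    return(c(mlp_grad_flatten(model$params$main, rvq),
             mlp_grad_flatten(model$params$hyper, rvh)))
  }
  # hypernetwork: per-case reverse through f_m, then through f_h
  fwh <- cache$fwh
  gidx <- cache$gidx
  n_case <- nrow(cache$ucase)
  lam_vids <- c(ss_var_id(ss, "A"), ss_var_id(ss, "sigma"))
  lam_vids <- lam_vids[!is.na(lam_vids)]
  n_theta <- mlp_n_params(model$params$main_proto)
  h_adj <- vector("list", ss$n_states)
  h_adj[[1L]] <- matrix(0, n_case, n_theta)
  for (vid in lam_vids) h_adj[[vid]] <- matrix(0, n_case, n_theta)
  for (ci in seq_len(n_case)) {
    sel <- which(gidx == ci)
    adj_c <- lapply(adj, function(m) if (is.null(m)) NULL else m[sel, , drop = FALSE])
    pm <- cache$case_params[[ci]]
    wt <- cache$case_wt[[ci]]
    rv <- mlp_reverse_states(pm, cache$case_caches[[ci]], adj_c, ss, wt = wt)
    h_adj[[1L]][ci, ] <- mlp_grad_flatten(pm, rv)
    if (length(lam_vids) && !is.null(rv$gWd)) {
      for (vid in lam_vids) {
        key <- as.character(vid)
        gt <- list(gW = lapply(rv$gWd, function(g) g$W[[key]]),
                   gb = lapply(rv$gWd, function(g) g$b[[key]]))
        h_adj[[vid]][ci, ] <- mlp_grad_flatten(pm, gt)
      }
    }
  }
  rvh <- mlp_reverse_states(model$params$hyper, fwh$cache, h_adj, ss)
  mlp_grad_flatten(model$params$hyper, rvh)
}

#' Predict flow variables at points
#'
#' @param model a `pinn_model`.
#' @param x,y coordinates (m).
#' @param case a [case_parameters()] or per-point data.frame.
#' @return data.frame with `u`, `v` (m/s) and `p` (Pa).
#' @export
predict_flow <- function(model, x, y, case) {
  ev <- flow_eval(model, x, y, case, ss_value())
  out <- as.data.frame(ev$states[[1L]])
  names(out) <- c("u", "v", "p")
  out
}

# ---------------------------------------------------------------------------
# Analytic reference fields
# ---------------------------------------------------------------------------

#' Construct an analytic flow field
#'
#' `fun(xt, yt, ss, ctx)` receives the coordinates as Taylor state bundles
#' and must return `list(u = , v = , p = )` of state bundles, so every
#' derivative the loss machinery requests is exact.
#'
#' @param fun field definition (see description).
#' @param ctx a [pinn_context()].
#' @param tag provenance tag stored with samples.
#' @return object of class `flow_field`.
#' @export
flow_field <- function(fun, ctx = pinn_context(), tag = "analytic") {
  structure(list(fun = fun, ctx = ctx, tag = tag), class = "flow_field")
}

#' @export
flow_eval.flow_field <- function(object, x, y, case, ss = ss_value(),
                                 wall_side = NULL, keep_cache = FALSE) {
  ctx <- object$ctx
  xt <- st_var(x, "x", ss)
  yt <- st_var(y, "y", ss)
  if (!is.null(wall_side) && any(wall_side != 0)) {
    cs <- expand_case(case, length(x))
    has_A <- !is.na(ss_var_id(ss, "A")); has_s <- !is.na(ss_var_id(ss, "sigma"))
    At <- if (has_A) st_var(cs$A, "A", ss) else st_const(cs$A, ss)
    sigt <- if (has_s) st_var(cs$sigma, "sigma", ss) else st_const(cs$sigma, ss)
    Rt <- radius_states(xt, At, sigt, ctx, ss)
    yw <- st_mul(st_const(rep_len(wall_side, length(x)), ss), Rt, ss)
    sel <- rep_len(wall_side, length(x)) != 0
    for (i in seq_along(yt)) {
      v <- yt[[i]]; v[sel] <- yw[[i]][sel]; yt[[i]] <- v
    }
  }
  f <- object$fun(xt, yt, ss, ctx)
  states <- lapply(seq_len(ss$n_states), function(si) {
    cbind(f$u[[si]], f$v[[si]], f$p[[si]])
  })
  list(states = states, cache = NULL)
}

#' Analytic straight-channel (Poiseuille) solution
#'
#' The exact steady solution in the A = 0 channel:
#' u = u_max (1 - y^2/R0^2), v = 0,
#' p = 2 rho nu u_max (length - x) / R0^2, so p(outlet) = 0.
#' It satisfies the incompressible Navier-Stokes equations and all boundary
#' conditions exactly and is used as the verification reference.
#'
#' @param ctx a [pinn_context()].
#' @return a [flow_field()].
#' @export
#' @examples
#' f <- analytic_straight_channel()
#' sample_flow_field(f, data.frame(x = c(0, 1), y = c(0, 0)))
analytic_straight_channel <- function(ctx = pinn_context()) {
  flow_field(function(xt, yt, ss, ctx) {
    R0 <- ctx$R0
    u <- st_scale(st_sub(st_const(1, ss), st_scale(st_mul(yt, yt, ss), 1 / R0^2)),
                  ctx$u_max)
    v <- st_scale(xt, 0)
    pgrad <- 2 * ctx$fluid$rho * ctx$fluid$nu * ctx$u_max / R0^2
    p <- st_scale(st_shift(st_scale(xt, -1), ctx$length), pgrad)
    list(u = u, v = v, p = p)
  }, ctx = ctx)
}

#' Sample a flow field at points
#'
#' @param field a `flow_field` or `pinn_model`.
#' @param points data.frame with `x`, `y`.
#' @param case case parameters (defaults to the straight channel).
#' @return data.frame `x, y, u, v, p` with a `provenance` attribute.
#' @export
sample_flow_field <- function(field, points, case = case_parameters(0, 0.134)) {
  ev <- flow_eval(field, points$x, points$y, case, ss_value())
  out <- data.frame(x = points$x, y = points$y,
                    u = ev$states[[1L]][, 1L], v = ev$states[[1L]][, 2L],
                    p = ev$states[[1L]][, 3L])
  attr(out, "provenance") <- if (inherits(field, "pinn_model")) "model" else field$tag
  out
}
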