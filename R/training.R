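# ---------------------------------------------------------------------------
# Multi-case optimization: collocation batching across cases, Adam updates,
# optional gradient-enhanced phase, convergence tracing, checkpoints.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param spec a [network_spec()].
#' @param ctx a [pinn_context()].
#' @param cases data.frame of training cases (`A`, `sigma`); default the
#'   single straight channel.
#' @param counts per-iteration region counts (default [default_batch_counts()],
#'   i.e. 3840 points per iteration).
#' @param iterations number of Adam iterations.
#' @param iterations_per_epoch interior pools are regenerated every this many
#'   iterations (default 1000; together with the default counts one epoch
#'   consumes 3.84 million spatial points).
#' @param pool_factor interior points are drawn from a pre-generated pool of
#'   `pool_factor` times the per-iteration interior count (default 1000).
#' @param lr,lr_min Adam learning rate with cosine decay from `lr` to
#'   `lr_min` over `iterations`.
#' @param betas Adam moment decay parameters.
#' @param weights a [loss_weights()] list.
#' @param gpinn_phase `"off"`, or a list
#'   `list(mode = "after_steps", iterations = n)` /
#'   `list(mode = "after_convergence", rel_change = 0.01, window = 5, iterations = n)`
#'   appending a derivative-loss phase after the plain phase.
#' @param seed integer seed controlling initialization and sampling.
#' @param trace_every record the loss breakdown every this many iterations.
#' @return object of class `training_config`.
#' @export
training_config <- function(spec, ctx = pinn_context(),
                            cases = data.frame(A = 0, sigma = 0.134),
                            counts = default_batch_counts(),
                            iterations = 1000L,
                            iterations_per_epoch = 1000L,
                            pool_factor = 1000L,
                            lr = 1e-3, lr_min = 1e-5,
                            betas = c(0.9, 0.999),
                            weights = loss_weights(),
                            gpinn_phase = "off",
                            seed = 1L,
                            trace_every = 50L) {
  stopifnot(inherits(spec, "network_spec"), sum(counts) > 0, lr > 0,
            nrow(cases) >= 1L)
  structure(list(spec = spec, ctx = ctx, cases = cases, counts = counts,
                 iterations = as.integer(iterations),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 pool_factor = as.integer(pool_factor),
                 lr = lr, lr_min = lr_min, betas = betas, weights = weights,
                 gpinn_phase = gpinn_phase, seed = as.integer(seed),
                 trace_every = as.integer(trace_every)),
            class = "training_config")
}

# split a per-iteration quota evenly across cases, remainder round-robin
split_quota <- function(n, n_cases, iter) {
  base <- n %/% n_cases
  rem <- n %% n_cases
  q <- rep(base, n_cases)
  if (rem > 0) {
    start <- (iter - 1L) %% n_cases
    idx <- (start + seq_len(rem) - 1L) %% n_cases + 1L
    q[idx] <- q[idx] + 1L
  }
  q
}

# sample one training batch across cases; interiors come from per-case pools
sample_batch <- function(cases, geoms, pools, counts, rng, iter) {
  n_cases <- nrow(cases)
  quotas <- lapply(REGIONS, function(r) split_quota(counts[[r]], n_cases, iter))
  names(quotas) <- REGIONS
  parts <- vector("list", n_cases)
  for (ci in seq_len(n_cases)) {
    geom <- geoms[[ci]]
    dfs <- list()
    ni <- quotas$interior[ci]
    if (ni > 0) {
      pool <- pools[[ci]]
      take <- rng$sample_int(nrow(pool), ni, replace = nrow(pool) < ni)
      dfs$interior <- data.frame(x = pool$x[take], y = pool$y[take],
                                 region = "interior")
    }
    bc <- function(region, n) {
      if (n == 0) return(NULL)
      switch(region,
        inlet = {
          R <- radius_profile(0, geom)
          data.frame(x = 0, y = rng$runif(n, -R, R), region = region)
        },
        outlet = {
          R <- radius_profile(geom$length, geom)
          data.frame(x = geom$length, y = rng$runif(n, -R, R), region = region)
        },
        wall_top = {
          x <- rng$runif(n, 0, geom$length)
          data.frame(x = x, y = radius_profile(x, geom), region = region)
        },
        wall_bottom = {
          x <- rng$runif(n, 0, geom$length)
          data.frame(x = x, y = -radius_profile(x, geom), region = region)
        })
    }
    for (r in setdiff(REGIONS, "interior")) dfs[[r]] <- bc(r, quotas[[r]][ci])
    part <- do.call(rbind, dfs)
    if (!is.null(part) && nrow(part)) {
      part$case_A <- cases$A[ci]; part$case_sigma <- cases$sigma[ci]
      part$case_index <- ci
    }
    parts[[ci]] <- part
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# loss breakdown + flattened parameter gradient for one batch
loss_and_grad <- function(model, batch, weights, gpinn = FALSE) {
  ctx <- model$ctx
  norms <- ctx$norms
  fluid <- ctx$fluid
  wphys <- weights$w_physics; wbc <- weights$w_bc
  wder <- if (gpinn) weights$w_derivative else 0
  lamw <- lambda_widths(ctx)
  grad <- 0
  parts <- list(continuity = NA_real_, momentum = NA_real_,
                wall_noslip = NA_real_, outlet_pressure = NA_real_,
                inlet_u = NA_real_, inlet_v = NA_real_,
                derivative_terms = if (gpinn) list() else NULL)

  intr <- batch[batch$region == "interior", , drop = FALSE]
  if (nrow(intr)) {
    ss <- if (gpinn) ss_gpinn() else ss_phys()
    ev <- flow_eval(model, intr$x, intr$y,
                    data.frame(A = intr$case_A, sigma = intr$case_sigma),
                    ss, keep_cache = TRUE)
    st <- ev$states
    res <- residuals_from_states(st, ss, fluid, lam = gpinn)
    N <- nrow(res)
    c_cont <- norms$V_s^2
    c_mom <- 1 / (norms$V_m / norms$V_s^2)^2
    parts$continuity <- c_cont * mean(res$continuity^2)
    parts$momentum <- c_mom * mean(res$momentum_x^2 + res$momentum_y^2)
    sid <- function(...) ss_state_id(ss, c(...))
    g <- function(...) st[[sid(...)]]
    adj <- vector("list", ss$n_states)
    addadj <- function(id, col, val) {
      if (is.null(adj[[id]])) adj[[id]] <<- matrix(0, N, 3L)
      adj[[id]][, col] <<- adj[[id]][, col] + val
    }
    u <- g()[, 1L]; v <- g()[, 2L]
    ux <- g("x")[, 1L]; vx <- g("x")[, 2L]
    uy <- g("y")[, 1L]; vy <- g("y")[, 2L]
    ca <- wphys * 2 * c_cont / N * res$continuity
    ma_x <- wphys * 2 * c_mom / N * res$momentum_x
    ma_y <- wphys * 2 * c_mom / N * res$momentum_y
    addadj(sid(), 1L, ma_x * ux + ma_y * vx)
    addadj(sid(), 2L, ma_x * uy + ma_y * vy)
    addadj(sid("x"), 1L, ca + ma_x * u)
    addadj(sid("x"), 2L, ma_y * u)
    addadj(sid("x"), 3L, ma_x / fluid$rho)
    addadj(sid("y"), 1L, ma_x * v)
    addadj(sid("y"), 2L, ca + ma_y * v)
    addadj(sid("y"), 3L, ma_y / fluid$rho)
    addadj(sid("x", "x"), 1L, -fluid$nu * ma_x)
    addadj(sid("x", "x"), 2L, -fluid$nu * ma_y)
    addadj(sid("y", "y"), 1L, -fluid$nu * ma_x)
    addadj(sid("y", "y"), 2L, -fluid$nu * ma_y)
    if (gpinn) {
      for (lv in c("A", "sigma")) {
        wl2 <- lamw[[lv]]^2
        contL <- res[[paste0("continuity_d", lv)]]
        momxL <- res[[paste0("momentum_x_d", lv)]]
        momyL <- res[[paste0("momentum_y_d", lv)]]
        parts$derivative_terms[[paste0("domain_", lv)]] <- wl2 *
          (c_cont * mean(contL^2) + c_mom * mean(momxL^2 + momyL^2))
        caL <- wder * 2 * wl2 * c_cont / N * contL
        maxL <- wder * 2 * wl2 * c_mom / N * momxL
        mayL <- wder * 2 * wl2 * c_mom / N * momyL
        uL <- g(lv)[, 1L]; vL <- g(lv)[, 2L]
        uxL <- g("x", lv)[, 1L]; vxL <- g("x", lv)[, 2L]
        uyL <- g("y", lv)[, 1L]; vyL <- g("y", lv)[, 2L]
        addadj(sid("x", lv), 1L, caL + maxL * u)
        addadj(sid("y", lv), 2L, caL + mayL * v)
        # momentum_x derivative
        addadj(sid(lv), 1L, maxL * ux)
        addadj(sid(), 1L, maxL * uxL)
        addadj(sid("x"), 1L, maxL * uL)
        addadj(sid(lv), 2L, maxL * uy)
        addadj(sid("y"), 1L, maxL * vL)
        addadj(sid(), 2L, maxL * uyL)
        addadj(sid("y", lv), 1L, maxL * v)
        addadj(sid("x", lv), 3L, maxL / fluid$rho)
        addadj(sid("x", "x", lv), 1L, -fluid$nu * maxL)
        addadj(sid("y", "y", lv), 1L, -fluid$nu * maxL)
        # momentum_y derivative
        addadj(sid(lv), 1L, mayL * vx)
        addadj(sid(), 1L, mayL * vxL)
        addadj(sid("x"), 2L, mayL * uL)
        addadj(sid(lv), 2L, mayL * vy)
        addadj(sid("y"), 2L, mayL * vL)
        addadj(sid(), 2L, mayL * vyL)
        addadj(sid("x", lv), 2L, mayL * u)
        addadj(sid("y", lv), 3L, mayL / fluid$rho)
        addadj(sid("x", "x", lv), 2L, -fluid$nu * mayL)
        addadj(sid("y", "y", lv), 2L, -fluid$nu * mayL)
      }
    }
    grad <- grad + pinn_grad(model, ev$cache, adj, ss)
  }

  bdry <- batch[batch$region != "interior", , drop = FALSE]
  if (nrow(bdry)) {
    ssb <- if (gpinn) ss_bc_gpinn() else ss_value()
    side <- ifelse(bdry$region == "wall_top", 1,
                   ifelse(bdry$region == "wall_bottom", -1, 0))
    ev <- flow_eval(model, bdry$x, bdry$y,
                    data.frame(A = bdry$case_A, sigma = bdry$case_sigma),
                    ssb, wall_side = side, keep_cache = TRUE)
    st <- ev$states
    Nb <- nrow(bdry)
    Y <- st[[1L]]
    adj <- vector("list", ssb$n_states)
    adj[[1L]] <- matrix(0, Nb, 3L)
    is_wall <- side != 0
    is_out <- bdry$region == "outlet"
    is_in <- bdry$region == "inlet"
    Vu2 <- norms$V_u^2; Vp2 <- norms$V_p^2
    if (any(is_wall)) {
      Nw <- sum(is_wall)
      parts$wall_noslip <- mean(Y[is_wall, 1L]^2 + Y[is_wall, 2L]^2) / Vu2
      adj[[1L]][is_wall, 1L] <- wbc * 2 / (Nw * Vu2) * Y[is_wall, 1L]
      adj[[1L]][is_wall, 2L] <- wbc * 2 / (Nw * Vu2) * Y[is_wall, 2L]
    }
    if (any(is_out)) {
      No <- sum(is_out)
      parts$outlet_pressure <- mean(Y[is_out, 3L]^2) / Vp2
      adj[[1L]][is_out, 3L] <- wbc * 2 / (No * Vp2) * Y[is_out, 3L]
    }
    if (any(is_in)) {
      Ni <- sum(is_in)
      tgt <- inlet_target(bdry$y[is_in], bdry$case_A[is_in],
                          bdry$case_sigma[is_in], ctx)
      du <- Y[is_in, 1L] - tgt
      parts$inlet_u <- mean(du^2) / Vu2
      parts$inlet_v <- mean(Y[is_in, 2L]^2) / Vu2
      adj[[1L]][is_in, 1L] <- wbc * 2 / (Ni * Vu2) * du
      adj[[1L]][is_in, 2L] <- wbc * 2 / (Ni * Vu2) * Y[is_in, 2L]
    }
    if (gpinn) {
      for (lv in c("A", "sigma")) {
        wl2 <- lamw[[lv]]^2
        vid <- ss_state_id(ssb, lv)
        dl <- st[[vid]]
        if (is.null(adj[[vid]])) adj[[vid]] <- matrix(0, Nb, 3L)
        term <- 0
        if (any(is_wall)) {
          Nw <- sum(is_wall)
          term <- term + wl2 * mean(dl[is_wall, 1L]^2 + dl[is_wall, 2L]^2) / Vu2
          adj[[vid]][is_wall, 1L] <- wder * 2 * wl2 / (Nw * Vu2) * dl[is_wall, 1L]
          adj[[vid]][is_wall, 2L] <- wder * 2 * wl2 / (Nw * Vu2) * dl[is_wall, 2L]
        }
        if (any(is_out)) {
          No <- sum(is_out)
          term <- term + wl2 * mean(dl[is_out, 3L]^2) / Vp2
          adj[[vid]][is_out, 3L] <- wder * 2 * wl2 / (No * Vp2) * dl[is_out, 3L]
        }
        if (any(is_in)) {
          Ni <- sum(is_in)
          dd <- dl[is_in, 1L]
          term <- term + wl2 * mean(dd^2 + dl[is_in, 2L]^2) / Vu2
          adj[[vid]][is_in, 1L] <- wder * 2 * wl2 / (Ni * Vu2) * dd
          adj[[vid]][is_in, 2L] <- wder * 2 * wl2 / (Ni * Vu2) * dl[is_in, 2L]
        }
        parts$derivative_terms[[paste0("boundary_", lv)]] <- term
      }
    }
    grad <- grad + pinn_grad(model, ev$cache, adj, ssb)
  }

  parts <- structure(parts, class = "loss_breakdown")
  parts$total <- total_loss(parts, modifyList(weights, list(
    w_derivative = if (gpinn) weights$w_derivative else 0)))
  list(parts = parts, grad = grad)
}

# one Adam state step; returns list(theta, m, v)
adam_step <- function(theta, grad, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- betas[1] * state$m + (1 - betas[1]) * grad
  state$v <- betas[2] * state$v + (1 - betas[2]) * grad^2
  mhat <- state$m / (1 - betas[1]^state$t)
  vhat <- state$v / (1 - betas[2]^state$t)
  state$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

cosine_lr <- function(iter, total, lr, lr_min) {
  if (total <= 1L) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (iter - 1L) / (total - 1L)))
}

trace_row <- function(step, parts, elapsed, phase) {
  dsum <- if (!is.null(parts$derivative_terms)) sum(unlist(parts$derivative_terms)) else NA_real_
  data.frame(step = step, continuity = parts$continuity,
             momentum = parts$momentum, wall_noslip = parts$wall_noslip,
             outlet_pressure = parts$outlet_pressure,
             inlet_u = parts$inlet_u, inlet_v = parts$inlet_v,
             derivative = dsum, total = parts$total,
             elapsed = elapsed, phase = phase)
}

#' Train a multi-case PINN
#'
#' Each iteration samples the configured per-region point counts (interior
#' points from per-case pre-generated pools, regenerated every epoch),
#' splits them across the training cases, evaluates the weighted
#' unit-normalized loss and applies one Adam step with cosine learning-rate
#' decay.  Fully reproducible given the config seed.  If the config requests
#' a gPINN phase, it is appended via [train_gpinn_phase()] after the plain
#' phase.
#'
#' @param config a [training_config()].
#' @param model optional `pinn_model` to resume from (default: freshly
#'   initialized from the config seed).
#' @param gpinn train with the derivative loss active from the start
#'   (used internally by [train_gpinn_phase()]).
#' @return list with `model` (trained) and `trace` (data.frame of loss
#'   breakdowns by step, with `phase` markers).
#' @export
train_pinn <- function(config, model = NULL, gpinn = FALSE) {
  stopifnot(inherits(config, "training_config"))
  phase <- if (gpinn) "gpinn" else "plain"
  if (is.null(model)) model <- init_model(config$spec, config$ctx, config$seed)
  theta <- model_flatten(model)
  opt <- model$meta$opt
  if (is.null(opt)) {
    opt <- list(theta = theta, m = theta * 0, v = theta * 0, t = 0L)
  }
  rng <- local_rng(config$seed + 1L)
  cases <- config$cases
  geoms <- lapply(seq_len(nrow(cases)), function(ci) {
    ctx_geometry(config$ctx, list(A = cases$A[ci], sigma = cases$sigma[ci]))
  })
  n_cases <- nrow(cases)
  counts <- config$counts
  if (is.null(names(counts))) names(counts) <- REGIONS
  int_quota <- max(split_quota(counts[["interior"]], n_cases, 1L))
  pools <- NULL
  trace <- list()
  t0 <- proc.time()[["elapsed"]]
  initial_total <- NA_real_
  diverged <- 0L
  step0 <- model$meta$iterations
  for (iter in seq_len(config$iterations)) {
    if (is.null(pools) || (iter - 1L) %% config$iterations_per_epoch == 0L) {
      pools <- lapply(seq_len(n_cases), function(ci) {
        n_pool <- max(1L, config$pool_factor * int_quota)
        collocation_pool(geoms[[ci]], n_pool,
                         seed = config$seed + 1000L * ci +
                           (iter - 1L) %/% config$iterations_per_epoch)
      })
    }
    batch <- sample_batch(cases, geoms, pools, counts, rng, iter)
    lg <- loss_and_grad(model, batch, config$weights, gpinn = gpinn)
    if (!all(is.finite(lg$grad))) stop("non-finite gradient at step ", step0 + iter)
    if (is.na(initial_total)) initial_total <- lg$parts$total
    if (is.finite(initial_total) && lg$parts$total > 1e6 * initial_total) {
      diverged <- diverged + 1L
      if (diverged >= 100L) {
        stop("training diverged: total loss exceeded 1e6 x initial for 100 consecutive steps")
      }
    } else diverged <- 0L
    lr <- cosine_lr(iter, config$iterations, config$lr, config$lr_min)
    opt <- adam_step(theta, lg$grad, opt, lr, config$betas)
    theta <- opt$theta
    model <- model_unflatten(model, theta)
    if (iter %% config$trace_every == 0L || iter == 1L || iter == config$iterations) {
      trace[[length(trace) + 1L]] <-
        trace_row(step0 + iter, lg$parts, proc.time()[["elapsed"]] - t0, phase)
    }
  }
  model$meta$iterations <- step0 + config$iterations
  model$meta$opt <- opt
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), continuity = numeric(), momentum = numeric(),
               wall_noslip = numeric(), outlet_pressure = numeric(),
               inlet_u = numeric(), inlet_v = numeric(),
               derivative = numeric(), total = numeric(),
               elapsed = numeric(), phase = character())
  result <- list(model = model, trace = trace)
  if (!gpinn && is.list(config$gpinn_phase) &&
      !identical(config$gpinn_phase, "off")) {
    gp_iters <- config$gpinn_phase$iterations %||% config$iterations
    gp_cfg <- config
    gp_cfg$iterations <- as.integer(gp_iters)
    gp <- train_gpinn_phase(result$model, gp_cfg)
    result$model <- gp$model
    result$trace <- rbind(result$trace, gp$trace)
  }
  result
}

#' Resume training with the gPINN derivative loss active
#'
#' Restarts optimization from a pre-trained model with the case-derivative
#' loss added; the activation step is visible in the trace via the `phase`
#' marker changing to `"gpinn"`.
#'
#' @param model a trained `pinn_model`.
#' @param config a [training_config()] describing the derivative phase
#'   (its `iterations` count applies to this phase).
#' @return list with `model` and `trace` (phase column set to `"gpinn"`).
#' @export
train_gpinn_phase <- function(model, config) {
  train_pinn(config, model = model, gpinn = TRUE)
}

# ---------------------------------------------------------------------------
# Checkpoints
# ---------------------------------------------------------------------------

CKPT_SCHEMA <- "tubepinn-checkpoint-1"

#' Save / load a model checkpoint
#'
#' The checkpoint restores parameters bit-exactly and the trace losslessly;
#' files carry a schema tag and an md5 integrity checksum, so truncated or
#' corrupted files raise an explicit error.
#'
#' @param model a `pinn_model`.
#' @param path file path.
#' @param trace optional convergence trace to store alongside.
#' @return `load_checkpoint` returns `list(model, trace)`.
#' @export
save_checkpoint <- function(model, path, trace = NULL) {
  payload <- serialize(list(model = model, trace = trace), NULL, xdr = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(payload, tmp)
  md5 <- unname(tools::md5sum(tmp))
  saveRDS(list(schema = CKPT_SCHEMA, md5 = md5, payload = payload), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("checkpoint unreadable: ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$schema, CKPT_SCHEMA)) {
    stop("not a tubepinn checkpoint (schema mismatch)")
  }
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(obj$payload, tmp)
  if (!identical(unname(tools::md5sum(tmp)), obj$md5)) {
    stop("checkpoint integrity check failed (md5 mismatch)")
  }
  unserialize(obj$payload)
}
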