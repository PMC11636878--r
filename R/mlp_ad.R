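# ---------------------------------------------------------------------------
# Forward propagation of derivative states through an MLP, and the matching
# reverse pass for parameter gradients.
#
# A "state bundle" is a list of N x width matrices, one per state of a
# state_set (value, first derivatives, selected second/third derivatives of
# every neuron with respect to the differentiation variables).  Affine
# layers may additionally carry first-order parameter tangents (`wt`), used
# by the hypernetwork whose main-network weights depend on the case
# parameters.
# ---------------------------------------------------------------------------

# wt: NULL, or list over layers of list(W = list keyed by singleton state id
# (as character) -> matrix, b = same -> vector)
mlp_forward_states <- function(p, X_states, ss, wt = NULL, keep_cache = FALSE) {
  L <- length(p$W)
  A <- X_states
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    W <- p$W[[l]]; b <- p$b[[l]]
    wtl <- if (!is.null(wt)) wt[[l]] else NULL
    Z <- vector("list", ss$n_states)
    for (ai in seq_len(ss$n_states)) {
      plan <- ss$mul_plan[[ai]]
      acc <- NULL
      for (r in seq_len(nrow(plan))) {
        gi <- plan$gi[r]
        Wg <- if (gi == 1L) W else {
          if (is.null(wtl)) next
          wtl$W[[as.character(gi)]]
        }
        if (is.null(Wg)) next
        term <- A[[plan$bi[r]]] %*% Wg
        if (plan$mult[r] != 1L) term <- term * plan$mult[r]
        acc <- if (is.null(acc)) term else acc + term
      }
      if (is.null(acc)) acc <- matrix(0, nrow(A[[1L]]), ncol(W))
      Z[[ai]] <- acc
    }
    if (!is.null(b)) Z[[1L]] <- sweep(Z[[1L]], 2L, b, "+")
    if (!is.null(wtl) && length(wtl$b)) {
      for (k in names(wtl$b)) {
        ki <- as.integer(k)
        Z[[ki]] <- sweep(Z[[ki]], 2L, wtl$b[[k]], "+")
      }
    }
    if (keep_cache) cache[[l]] <- list(A_in = A, Z = Z)
    if (l < L) {
      fd <- silu_derivs(Z[[1L]], upto = 3L)
      A <- st_chain(Z, fd, ss)
    } else {
      A <- Z
    }
  }
  list(out = A, cache = cache)
}

# reverse pass: out_adj is a state bundle of adjoints on the network output
# (NULL entries = zero).  Returns per-layer weight/bias gradients, gradients
# of any weight tangents, and the adjoint bundle of the inputs.
mlp_reverse_states <- function(p, cache, out_adj, ss, wt = NULL,
                               want_input_adj = FALSE) {
  L <- length(p$W)
  gW <- vector("list", L); gb <- vector("list", L)
  gWd <- if (!is.null(wt)) vector("list", L) else NULL
  Zadj <- out_adj
  for (l in rev(seq_len(L))) {
    W <- p$W[[l]]
    wtl <- if (!is.null(wt)) wt[[l]] else NULL
    A <- cache[[l]]$A_in
    gW[[l]] <- matrix(0, nrow(W), ncol(W))
    if (!is.null(p$b[[l]])) gb[[l]] <- numeric(ncol(W))
    if (!is.null(wtl)) {
      gWd[[l]] <- list(W = lapply(wtl$W, function(m) m * 0),
                       b = lapply(wtl$b, function(v) v * 0))
    }
    Aadj <- vector("list", ss$n_states)
    for (ai in seq_len(ss$n_states)) {
      za <- Zadj[[ai]]
      if (is.null(za)) next
      plan <- ss$mul_plan[[ai]]
      for (r in seq_len(nrow(plan))) {
        gi <- plan$gi[r]; bi <- plan$bi[r]; mult <- plan$mult[r]
        if (gi == 1L) {
          contrib <- crossprod(A[[bi]], za)
          gW[[l]] <- gW[[l]] + if (mult == 1L) contrib else mult * contrib
          down <- za %*% t(W)
        } else {
          if (is.null(wtl)) next
          key <- as.character(gi)
          Wg <- wtl$W[[key]]
          if (is.null(Wg)) next
          contrib <- crossprod(A[[bi]], za)
          gWd[[l]]$W[[key]] <- gWd[[l]]$W[[key]] +
            if (mult == 1L) contrib else mult * contrib
          down <- za %*% t(Wg)
        }
        if (mult != 1L) down <- down * mult
        Aadj[[bi]] <- if (is.null(Aadj[[bi]])) down else Aadj[[bi]] + down
      }
    }
    if (!is.null(p$b[[l]])) gb[[l]] <- colSums(Zadj[[1L]] %||% matrix(0, 1L, ncol(W)))
    if (!is.null(wtl) && length(wtl$b)) {
      for (k in names(wtl$b)) {
        ki <- as.integer(k)
        if (!is.null(Zadj[[ki]])) gWd[[l]]$b[[k]] <- colSums(Zadj[[ki]])
      }
    }
    if (l > 1L) {
      Zprev <- cache[[l - 1L]]$Z
      fd <- silu_derivs(Zprev[[1L]], upto = 4L)
      Zadj <- st_chain_rev(Zprev, fd[-1L], Aadj, ss)
    } else if (want_input_adj) {
      Zadj <- Aadj
    } else {
      Zadj <- NULL
    }
  }
  list(gW = gW, gb = gb, gWd = gWd, input_adj = Zadj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten per-layer gradients in the same order as mlp_flatten
mlp_grad_flatten <- function(p, grads) {
  unlist(lapply(seq_along(p$W), function(l) {
    c(as.numeric(grads$gW[[l]]),
      if (!is.null(p$b[[l]])) grads$gb[[l]] %||% numeric(length(p$b[[l]])))
  }))
}
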