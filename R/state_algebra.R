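# ---------------------------------------------------------------------------
# Truncated-Taylor "state" algebra.
#
# A quantity is represented by a list of arrays ("states"), one per retained
# derivative multi-index: the value, first derivatives with respect to a set
# of differentiation variables, and selected second- and third-order
# derivatives.  All propagation rules (Leibniz products, univariate chain
# rule to third order, affine maps with parameter tangents) are driven by
# plans precomputed once per state set, so the same kernels serve the
# geometry features, the SiLU network layers, and the reverse pass that
# accumulates parameter gradients.
# ---------------------------------------------------------------------------

# ("0" = the value state; empty names cannot be used for named lookup in R)
state_key <- function(idx) if (length(idx) == 0L) "0" else paste(idx, collapse = ".")

#' Define a derivative state set
#'
#' Declares which derivatives are carried through every computation: the
#' value, first derivatives with respect to `vars`, and the listed second-
#' (`pairs`) and third-order (`triples`) derivatives.  The set must be closed
#' under taking sub-multi-indices (every pair of a triple must be listed,
#' etc.); this is validated at construction.
#'
#' @param vars character vector of differentiation variable names
#'   (subset of `x`, `y`, `A`, `sigma` in practice).
#' @param pairs 2-column matrix of indices into `vars` (rows sorted).
#' @param triples 3-column matrix of indices into `vars` (rows sorted).
#' @return an object of class `state_set` with precomputed product and
#'   chain-rule plans.
#' @keywords internal
state_set <- function(vars = character(), pairs = NULL, triples = NULL) {
  nv <- length(vars)
  norm_rows <- function(m, k) {
    if (is.null(m)) return(matrix(integer(), 0L, k))
    m <- matrix(as.integer(m), ncol = k)
    t(apply(m, 1L, sort))
  }
  pairs <- norm_rows(pairs, 2L)
  triples <- norm_rows(triples, 3L)
  states <- list(integer(0))
  if (nv > 0L) states <- c(states, lapply(seq_len(nv), function(i) i))
  if (nrow(pairs)) states <- c(states, lapply(seq_len(nrow(pairs)), function(r) pairs[r, ]))
  if (nrow(triples)) states <- c(states, lapply(seq_len(nrow(triples)), function(r) triples[r, ]))
  keys <- vapply(states, state_key, "")
  if (anyDuplicated(keys)) stop("duplicate states in state_set")
  id <- stats::setNames(seq_along(states), keys)
  # closure: every sub-multiset of every state must be present
  for (s in states) {
    if (length(s) < 2L) next
    for (drop in seq_along(s)) {
      sub <- state_key(sort(s[-drop]))
      if (is.na(id[sub])) {
        stop("state_set not closed: missing sub-state {", sub, "} of {", state_key(s), "}")
      }
    }
  }
  orders <- lengths(states)

  # product (Leibniz) plan: for each target state, all splits (beta, gamma)
  # with multiplicity, enumerated over subsets of derivative "slots"
  mul_plan <- lapply(seq_along(states), function(ai) {
    a <- states[[ai]]
    n <- length(a)
    subs <- if (n == 0L) list(integer(0)) else {
      out <- list()
      for (m in 0:n) out <- c(out, utils::combn(n, m, simplify = FALSE))
      out
    }
    rows <- lapply(subs, function(pos) {
      b <- sort(a[pos]); g <- sort(a[setdiff(seq_len(n), pos)])
      c(bi = unname(id[state_key(b)]), gi = unname(id[state_key(g)]))
    })
    df <- as.data.frame(do.call(rbind, rows))
    agg <- stats::aggregate(list(mult = rep(1L, nrow(df))), df, sum)
    agg
  })

  # chain-rule structure for pairs and triples
  pair_info <- NULL
  if (nrow(pairs)) {
    pair_info <- lapply(seq_len(nrow(pairs)), function(r) {
      p <- pairs[r, ]
      list(ai = unname(id[state_key(p)]),
           s1 = unname(id[state_key(p[1])]),
           s2 = unname(id[state_key(p[2])]))
    })
  }
  triple_info <- NULL
  if (nrow(triples)) {
    triple_info <- lapply(seq_len(nrow(triples)), function(r) {
      tr <- triples[r, ]
      sing <- vapply(tr, function(v) unname(id[state_key(v)]), 1L)
      # pairings of 3 slots into pair + singleton
      combos <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
      prs <- lapply(combos, function(cmb) {
        c(pair = unname(id[state_key(sort(tr[cmb[1:2]]))]),
          sing = unname(id[state_key(tr[cmb[3]])]))
      })
      df <- as.data.frame(do.call(rbind, prs))
      agg <- stats::aggregate(list(mult = rep(1L, nrow(df))), df, sum)
      list(ai = unname(id[state_key(tr)]), sing = sing, pairings = agg)
    })
  }

  structure(list(vars = vars, states = states, keys = keys, id = id,
                 orders = orders, n_states = length(states),
                 mul_plan = mul_plan, pair_info = pair_info,
                 triple_info = triple_info),
            class = "state_set")
}

# state id for a derivative multi-index given as variable names
ss_state_id <- function(ss, vars_chr) {
  idx <- match(vars_chr, ss$vars)
  if (anyNA(idx)) return(NA_integer_)
  unname(ss$id[state_key(sort(idx))])
}

ss_var_id <- function(ss, var) {
  i <- match(var, ss$vars)
  if (is.na(i)) return(NA_integer_)
  unname(ss$id[state_key(i)])
}

# --- constructors -----------------------------------------------------------

st_const <- function(val, ss) {
  out <- vector("list", ss$n_states)
  out[[1L]] <- val
  z <- val * 0
  for (i in seq_len(ss$n_states)[-1L]) out[[i]] <- z
  out
}

st_var <- function(val, var, ss, seed = 1) {
  out <- st_const(val, ss)
  vid <- ss_var_id(ss, var)
  if (!is.na(vid)) out[[vid]] <- val * 0 + seed
  out
}

# --- arithmetic -------------------------------------------------------------

st_add <- function(a, b) Map(`+`, a, b)
st_sub <- function(a, b) Map(`-`, a, b)
st_scale <- function(a, k) lapply(a, function(m) m * k)
st_shift <- function(a, k) { a[[1L]] <- a[[1L]] + k; a }

st_mul <- function(a, b, ss) {
  out <- vector("list", ss$n_states)
  for (ai in seq_len(ss$n_states)) {
    plan <- ss$mul_plan[[ai]]
    acc <- 0
    for (r in seq_len(nrow(plan))) {
      term <- a[[plan$bi[r]]] * b[[plan$gi[r]]]
      acc <- acc + if (plan$mult[r] == 1L) term else plan$mult[r] * term
    }
    out[[ai]] <- acc
  }
  out
}

# division: solve a = w * b for w, in increasing state order
st_div <- function(a, b, ss) {
  out <- vector("list", ss$n_states)
  inv_b <- 1 / b[[1L]]
  out[[1L]] <- a[[1L]] * inv_b
  for (ai in seq_len(ss$n_states)[-1L]) {
    plan <- ss$mul_plan[[ai]]
    acc <- a[[ai]]
    for (r in seq_len(nrow(plan))) {
      if (plan$bi[r] == ai) next  # the unknown term w_alpha * b_value
      term <- out[[plan$bi[r]]] * b[[plan$gi[r]]]
      acc <- acc - if (plan$mult[r] == 1L) term else plan$mult[r] * term
    }
    out[[ai]] <- acc * inv_b
  }
  out
}

# univariate chain rule to third order; fd = list(f0, f1, f2, f3) at u value
st_chain <- function(u, fd, ss) {
  out <- vector("list", ss$n_states)
  out[[1L]] <- fd[[1L]]
  nv <- length(ss$vars)
  for (v in seq_len(nv)) {
    vid <- unname(ss$id[state_key(v)])
    out[[vid]] <- fd[[2L]] * u[[vid]]
  }
  if (!is.null(ss$pair_info)) {
    for (pi in ss$pair_info) {
      out[[pi$ai]] <- fd[[3L]] * u[[pi$s1]] * u[[pi$s2]] + fd[[2L]] * u[[pi$ai]]
    }
  }
  if (!is.null(ss$triple_info)) {
    for (ti in ss$triple_info) {
      acc <- fd[[4L]] * u[[ti$sing[1L]]] * u[[ti$sing[2L]]] * u[[ti$sing[3L]]]
      pg <- ti$pairings
      for (r in seq_len(nrow(pg))) {
        term <- u[[pg$pair[r]]] * u[[pg$sing[r]]]
        acc <- acc + fd[[3L]] * if (pg$mult[r] == 1L) term else pg$mult[r] * term
      }
      out[[ti$ai]] <- acc + fd[[2L]] * u[[ti$ai]]
    }
  }
  out
}

# reverse (adjoint) of st_chain; fd = list(f1, f2, f3, f4) at u value.
# adj may contain NULLs (treated as zero).  Returns adjoint states of u.
st_chain_rev <- function(u, fd, adj, ss) {
  zero <- u[[1L]] * 0
  g <- function(i) if (is.null(adj[[i]])) NULL else adj[[i]]
  ubar <- vector("list", ss$n_states)
  addto <- function(i, val) {
    if (is.null(ubar[[i]])) ubar[[i]] <<- val else ubar[[i]] <<- ubar[[i]] + val
  }
  # value adjoint accumulates from every output state's dependence on u value
  a0 <- g(1L)
  if (!is.null(a0)) addto(1L, fd[[1L]] * a0)
  nv <- length(ss$vars)
  for (v in seq_len(nv)) {
    vid <- unname(ss$id[state_key(v)])
    av <- g(vid)
    if (is.null(av)) next
    addto(1L, fd[[2L]] * u[[vid]] * av)     # d out_v / d u0 = f2 * u_v
    addto(vid, fd[[1L]] * av)               # d out_v / d u_v = f1
  }
  if (!is.null(ss$pair_info)) {
    for (pi in ss$pair_info) {
      ap <- g(pi$ai)
      if (is.null(ap)) next
      addto(1L, (fd[[3L]] * u[[pi$s1]] * u[[pi$s2]] + fd[[2L]] * u[[pi$ai]]) * ap)
      addto(pi$s1, fd[[2L]] * u[[pi$s2]] * ap)
      addto(pi$s2, fd[[2L]] * u[[pi$s1]] * ap)
      addto(pi$ai, fd[[1L]] * ap)
    }
  }
  if (!is.null(ss$triple_info)) {
    for (ti in ss$triple_info) {
      at <- g(ti$ai)
      if (is.null(at)) next
      u1 <- u[[ti$sing[1L]]]; u2 <- u[[ti$sing[2L]]]; u3 <- u[[ti$sing[3L]]]
      pg <- ti$pairings
      # u value
      acc0 <- fd[[4L]] * u1 * u2 * u3
      for (r in seq_len(nrow(pg))) {
        acc0 <- acc0 + fd[[3L]] * pg$mult[r] * u[[pg$pair[r]]] * u[[pg$sing[r]]]
      }
      acc0 <- acc0 + fd[[2L]] * u[[ti$ai]]
      addto(1L, acc0 * at)
      # singleton adjoints from the f3*u1*u2*u3 term (slot-wise)
      addto(ti$sing[1L], fd[[3L]] * u2 * u3 * at)
      addto(ti$sing[2L], fd[[3L]] * u1 * u3 * at)
      addto(ti$sing[3L], fd[[3L]] * u1 * u2 * at)
      # pairings term f2 * mult * u_pair * u_sing
      for (r in seq_len(nrow(pg))) {
        addto(pg$pair[r], fd[[2L]] * pg$mult[r] * u[[pg$sing[r]]] * at)
        addto(pg$sing[r], fd[[2L]] * pg$mult[r] * u[[pg$pair[r]]] * at)
      }
      addto(ti$ai, fd[[1L]] * at)
    }
  }
  for (i in seq_len(ss$n_states)) if (is.null(ubar[[i]])) ubar[[i]] <- zero
  ubar
}

st_exp <- function(u, ss) {
  e <- exp(u[[1L]])
  st_chain(u, list(e, e, e, e), ss)
}

st_square <- function(u, ss) st_mul(u, u, ss)

# evaluate a state list at given orders via finite differences (test helper
# lives in tests; here only a convenience extractor)
st_get <- function(s, ss, idx) {
  s[[unname(ss$id[state_key(sort(idx))])]]
}

# --- commonly used state sets ----------------------------------------------

# value only
ss_value <- function() state_set(character())

# first derivatives in x, y (wall shear stress, continuity-only uses)
ss_grad_xy <- function() state_set(c("x", "y"))

# physics residuals: u_x, u_y, u_xx, u_yy
ss_phys <- function() {
  state_set(c("x", "y"), pairs = rbind(c(1, 1), c(2, 2)))
}

# gPINN: physics states plus first case derivatives and the mixed orders
# needed for d(residual)/d(lambda)
ss_gpinn <- function() {
  state_set(c("x", "y", "A", "sigma"),
            pairs = rbind(c(1, 1), c(2, 2),
                          c(1, 3), c(2, 3), c(1, 4), c(2, 4)),
            triples = rbind(c(1, 1, 3), c(2, 2, 3), c(1, 1, 4), c(2, 2, 4)))
}

# boundary-condition lambda derivatives: values + first derivatives
ss_bc_gpinn <- function() state_set(c("x", "y", "A", "sigma"))
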