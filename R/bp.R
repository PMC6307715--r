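# Belief propagation for the side-chain free energy.  The discrete problem
# is a pairwise Markov random field: 1-residue energy vectors v_i and
# 2-residue energy matrices v_ij on a neighbor graph.  Damped synchronous
# message passing yields node and pair marginals; the free energy is the
# Bethe form <v> - S_approx, where the entropy keeps node terms and pairwise
# mutual information only.  BP is exact on trees, which the test-suite
# exploits via an independent brute-force enumerator.

BELIEF_FLOOR <- 1e-300

.floored <- function(x) {
  x[x < BELIEF_FLOOR] <- BELIEF_FLOOR
  x
}

.check_discrete <- function(v, edges, v_ij) {
  stopifnot(is.list(v), all(vapply(v, function(x) all(is.finite(x)), TRUE)))
  if (length(v_ij)) {
    stopifnot(nrow(edges) == length(v_ij))
    for (e in seq_len(nrow(edges))) {
      stopifnot(nrow(v_ij[[e]]) == length(v[[edges[e, 1]]]),
                ncol(v_ij[[e]]) == length(v[[edges[e, 2]]]))
    }
  }
  invisible(TRUE)
}

.normalize_pos <- function(x) {
  x[x < BELIEF_FLOOR] <- BELIEF_FLOOR
  x / sum(x)
}

#' Initialize belief propagation
#'
#' Round-0 node beliefs are proportional to `exp(-v_i)`; round-0 edge
#' messages are the interaction-weighted sums of the neighbor beliefs.
#' Beliefs and messages are kept normalized (the fixed point is invariant
#' to message scale).
#'
#' @param v list of 1-residue energy vectors (kT).
#' @param edges integer matrix with columns (i, j), i < j.
#' @param v_ij list of energy matrices, one per edge row, dimension
#'   `length(v[[i]]) x length(v[[j]])`.
#' @return a `bp_state`: list of node beliefs `b`, directed edge messages
#'   `m_ji` (message into i) and `m_ij` (message into j), and `round`.
#' @export
bp_initialize <- function(v, edges, v_ij) {
  .check_discrete(v, edges, v_ij)
  b <- lapply(v, function(vi) .normalize_pos(exp(-(vi - min(vi)))))
  ne <- if (is.null(edges)) 0L else nrow(edges)
  m_ji <- vector("list", ne)
  m_ij <- vector("list", ne)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      W <- exp(-(v_ij[[e]] - min(v_ij[[e]])))
      m_ji[[e]] <- .normalize_pos(as.numeric(W %*% b[[j]]))
      m_ij[[e]] <- .normalize_pos(as.numeric(crossprod(W, b[[i]])))
    }
  }
  structure(list(b = b, m_ji = m_ji, m_ij = m_ij, round = 0L),
            class = "bp_state")
}

#' One synchronous round of damped belief propagation
#'
#' Edge messages are recomputed from the previous round's beliefs divided by
#' the opposing message (cavity construction); node beliefs are then mixed
#' with damping `lambda` (at `lambda = 1` the beliefs do not move).
#'
#' @param state a `bp_state` from [bp_initialize()] or a previous round.
#' @inheritParams bp_initialize
#' @param lambda damping constant in \code{[0, 1]}.
#' @return the updated `bp_state`.
#' @export
bp_iterate <- function(state, v, edges, v_ij, lambda = 0.4) {
  b <- state$b
  ne <- if (is.null(edges)) 0L else nrow(edges)
  new_ji <- vector("list", ne)
  new_ij <- vector("list", ne)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      W <- exp(-(v_ij[[e]] - min(v_ij[[e]])))
      cav_j <- b[[j]] / .floored(state$m_ij[[e]])
      cav_i <- b[[i]] / .floored(state$m_ji[[e]])
      new_ji[[e]] <- .normalize_pos(as.numeric(W %*% cav_j))
      new_ij[[e]] <- .normalize_pos(as.numeric(crossprod(W, cav_i)))
    }
  }
  nb <- vector("list", length(v))
  logm <- lapply(v, function(vi) -vi)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      logm[[i]] <- logm[[i]] + log(new_ji[[e]])
      logm[[j]] <- logm[[j]] + log(new_ij[[e]])
    }
  }
  for (i in seq_along(v)) {
    raw <- .normalize_pos(exp(logm[[i]] - max(logm[[i]])))
    nb[[i]] <- .normalize_pos(lambda * b[[i]] + (1 - lambda) * raw)
  }
  structure(list(b = nb, m_ji = new_ji, m_ij = new_ij,
                 round = state$round + 1L),
            class = "bp_state")
}

#' Solve for side-chain marginals by damped belief propagation
#'
#' Iterates [bp_iterate()] until the largest node-belief change is below
#' `tol` (the convergence criterion is on node beliefs only), then computes
#' node and pair marginals and the Bethe free energy.
#'
#' @inheritParams bp_iterate
#' @param tol convergence tolerance on node beliefs.
#' @param max_iter iteration cap; on hitting it the best state is returned
#'   with `converged = FALSE` rather than raising.
#' @param init optional `bp_state` to warm-start from (e.g. the previous
#'   dynamics frame).
#' @return a `marginal_set`: `p` (node marginals), `p_edges` (pair
#'   marginals per edge), `edges`, `G` (Bethe free energy, kT),
#'   `converged`, `iterations`, and the final `state` for warm starts.
#' @export
solve_marginals <- function(v, edges, v_ij, lambda = 0.4, tol = 1e-3,
                            max_iter = 1000L, init = NULL) {
  state <- if (is.null(init)) bp_initialize(v, edges, v_ij) else init
  converged <- FALSE
  iter <- 0L
  ne <- if (is.null(edges)) 0L else nrow(edges)
  repeat {
    iter <- iter + 1L
    nxt <- bp_iterate(state, v, edges, v_ij, lambda)
    delta <- 0
    for (i in seq_along(v)) {
      di <- max(abs(nxt$b[[i]] - state$b[[i]]))
      if (di > delta) delta <- di
    }
    state <- nxt
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  p <- state$b
  p_edges <- vector("list", ne)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      W <- exp(-(v_ij[[e]] - min(v_ij[[e]])))
      wi <- p[[i]] / .floored(state$m_ji[[e]])
      wj <- p[[j]] / .floored(state$m_ij[[e]])
      M <- (wi %o% wj) * W
      p_edges[[e]] <- M / sum(M)
    }
  }
  G <- bethe_free_energy(p, p_edges, v, edges, v_ij)
  structure(list(p = p, p_edges = p_edges, edges = edges, G = G,
                 converged = converged, iterations = iter, state = state),
            class = "marginal_set")
}

.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Bethe free energy from marginals
#'
#' `G = <v> - S_approx`, where the average energy uses the node and pair
#' marginals and the approximate entropy is the sum of node entropies minus
#' the edge mutual informations (0 log 0 = 0).
#'
#' @param p list of node marginal vectors.
#' @param p_edges list of pair marginal matrices per edge.
#' @inheritParams bp_initialize
#' @return free energy in kT.
#' @export
bethe_free_energy <- function(p, p_edges, v, edges, v_ij) {
  G <- 0
  for (i in seq_along(v)) {
    G <- G + sum(p[[i]] * v[[i]]) + sum(.xlogx(p[[i]]))
  }
  ne <- if (is.null(edges)) 0L else nrow(edges)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      pij <- p_edges[[e]]
      G <- G + sum(pij * v_ij[[e]])
      ref <- p[[i]] %o% p[[j]]
      mi <- sum(ifelse(pij > 0, pij * log(pij / pmax(ref, BELIEF_FLOOR)), 0))
      G <- G + mi
    }
  }
  G
}

#' Pairwise consistency checks on marginals
#'
#' Verifies marginalization (pair marginals sum to the node marginals),
#' normalization, and — where both orientations of an unordered pair are
#' supplied — symmetry.  Passing these checks does not imply the marginals
#' are representable by any joint distribution; the classic three-residue
#' counterexample (two perfectly correlated pairs plus an independent one)
#' passes them all.
#'
#' @inheritParams bethe_free_energy
#' @return list with `marginalization`, `normalization`, `symmetry`, and
#'   `max` (largest violation).
#' @export
check_consistency <- function(p, p_edges, edges) {
  ne <- if (is.null(edges)) 0L else nrow(edges)
  marg <- 0; norm <- 0; sym <- 0
  seen <- list()
  for (e in seq_len(ne)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    pij <- p_edges[[e]]
    norm <- max(norm, abs(sum(pij) - 1))
    marg <- max(marg, max(abs(rowSums(pij) - p[[i]])),
                max(abs(colSums(pij) - p[[j]])))
    key <- paste(sort(c(i, j)), collapse = "-")
    if (!is.null(seen[[key]])) {
      prev <- seen[[key]]
      if (prev$i == j && prev$j == i)
        sym <- max(sym, max(abs(pij - t(prev$p))))
    }
    seen[[key]] <- list(i = i, j = j, p = pij)
  }
  list(marginalization = marg, normalization = norm, symmetry = sym,
       max = max(marg, norm, sym))
}

#' Exact marginals and free energy by enumeration
#'
#' Brute-force summation over all joint states; the independent reference
#' for belief propagation.  Refuses state spaces above `10^7`.
#'
#' @inheritParams bp_initialize
#' @return list with exact `p`, `p_edges`, and `minus_logZ`.
#' @export
brute_force_reference <- function(v, edges, v_ij) {
  .check_discrete(v, edges, v_ij)
  ns <- vapply(v, length, integer(1))
  S <- prod(ns)
  if (S > 1e7) stop("state space too large for enumeration (", S, " states)")
  n <- length(v)
  stride <- cumprod(c(1, ns[-n]))
  ne <- if (is.null(edges)) 0L else nrow(edges)
  chunk <- 1e6
  L <- -Inf
  acc_p <- lapply(ns, numeric)
  acc_e <- lapply(seq_len(ne), function(e)
    matrix(0, ns[edges[e, 1]], ns[edges[e, 2]]))
  for (start in seq(0, S - 1, by = chunk)) {
    ids <- start:min(S - 1, start + chunk - 1)
    si <- matrix(0L, length(ids), n)
    for (k in seq_len(n)) si[, k] <- (ids %/% stride[k]) %% ns[k] + 1L
    E <- numeric(length(ids))
    for (k in seq_len(n)) E <- E + v[[k]][si[, k]]
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      E <- E + v_ij[[e]][cbind(si[, i], si[, j])]
    }
    lw <- -E
    Lc <- max(lw) + log(sum(exp(lw - max(lw))))
    w <- exp(lw - Lc)
    Lnew <- if (is.finite(L)) max(L, Lc) + log(exp(L - max(L, Lc)) +
                                               exp(Lc - max(L, Lc))) else Lc
    sc_old <- if (is.finite(L)) exp(L - Lnew) else 0
    sc_new <- exp(Lc - Lnew)
    for (k in seq_len(n)) {
      wk <- rowsum(w, si[, k])
      nk <- numeric(ns[k]); nk[as.integer(rownames(wk))] <- wk
      acc_p[[k]] <- acc_p[[k]] * sc_old + nk / sum(w) * sc_new
    }
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      grp <- si[, i] + (si[, j] - 1L) * ns[i]
      we <- rowsum(w, grp)
      m <- matrix(0, ns[i], ns[j])
      m[as.integer(rownames(we))] <- we
      acc_e[[e]] <- acc_e[[e]] * sc_old + m / sum(w) * sc_new
    }
    L <- Lnew
  }
  list(p = acc_p, p_edges = acc_e, minus_logZ = -L)
}
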