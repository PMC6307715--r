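# Maximum-likelihood training of the spline potential.  The loss per
# training example is the energy gap
#   E_gap = V(native states) - G^SC = -log p(native)
# under the Bethe approximation of G^SC, so minimizing the mean gap
# maximizes the likelihood of the crystallographic (here: planted) rotamer
# states.  Because the marginals minimize the free energy, the parametric
# gradient is the envelope expression
#   dE_gap/dtheta = dV(native)/dtheta - E_p[ dv/dtheta ],
# which is assembled from cached spline bases: for a fixed backbone the
# interaction geometry (r, cos theta1, cos theta2, hydrogen-bond gating)
# never changes, so training reduces to cheap linear algebra per Adam step.

#' Energy gap of a training example
#'
#' @param example a [training_example()].
#' @param params a `parameter_set`.
#' @param solver `"bp"` (belief propagation, as in inference) or
#'   `"exact"` (brute-force enumeration, for small systems).
#' @param per `"protein"` (total kT) or `"residue"` (divided by chain
#'   length).
#' @param lambda,tol,max_iter belief-propagation controls.
#' @param detail if TRUE return a list with the native energy, free energy
#'   and marginals.
#' @return the energy gap in kT (`-log p(native)`).
#' @export
energy_gap <- function(example, params, solver = c("bp", "exact"),
                       per = c("protein", "residue"),
                       lambda = 0.4, tol = 1e-3, max_iter = 1000L,
                       detail = FALSE) {
  solver <- match.arg(solver)
  per <- match.arg(per)
  sys <- sc_system(example$chain, params)
  nat <- example$native
  for (i in seq_along(nat))
    if (nat[i] < 1 || nat[i] > length(sys$v[[i]]))
      stop("invalid native state at residue ", i)
  Vn <- sum(vapply(seq_along(nat), function(i) sys$v[[i]][nat[i]], numeric(1)))
  ne <- if (is.null(sys$edges)) 0L else nrow(sys$edges)
  for (e in seq_len(ne))
    Vn <- Vn + sys$v_ij[[e]][nat[sys$edges[e, 1]], nat[sys$edges[e, 2]]]
  if (solver == "bp") {
    ms <- solve_marginals(sys$v, sys$edges, sys$v_ij, lambda = lambda,
                          tol = tol, max_iter = max_iter)
    G <- ms$G
  } else {
    bf <- brute_force_reference(sys$v, sys$edges, sys$v_ij)
    G <- bf$minus_logZ
    ms <- NULL
  }
  gap <- Vn - G
  if (per == "residue") gap <- gap / length(nat)
  if (detail) list(E_gap = gap, V_native = Vn, G = G, marginals = ms,
                   system = sys)
  else gap
}

#' Smoothness/size regularization of the spline potential
#'
#' Three penalties summed at the knot locations: squared second differences
#' of each isotropic radial curve (smoothness), squared directional
#' coefficients (keeping directional terms small), and the squared
#' deviation of each radial curve's contact knot from 5 kT (a strong steric
#' core).  The angular factors are penalized in log-coefficient space,
#' pulling them toward unit (neutral) coefficients while preserving
#' positivity.
#'
#' @param params a `parameter_set`.
#' @param weights named vector with elements `smooth`, `dir`, `core`.
#' @param keys pair-block keys to include (default all).
#' @return penalty value with attribute `"grad"`: its gradient in the
#'   [flatten_params()] layout.
#' @export
regularization <- function(params, weights = c(smooth = 1, dir = 1, core = 1),
                           keys = NULL) {
  lay <- param_layout(params, keys)
  gr <- numeric(attr(lay, "n"))
  val <- 0
  for (ent in lay) {
    pp <- params$pair[[ent$key]]
    cr <- pp$radial
    K <- length(cr)
    d2 <- 2 * cr[2:(K - 1)] - cr[1:(K - 2)] - cr[3:K]
    val <- val + weights["smooth"] * sum(d2^2)
    # gradient of sum d2^2 wrt cr (last knot pinned, dropped below)
    gd <- numeric(K)
    for (ii in seq_along(d2)) {
      gd[ii] <- gd[ii] - 2 * d2[ii]
      gd[ii + 1] <- gd[ii + 1] + 4 * d2[ii]
      gd[ii + 2] <- gd[ii + 2] - 2 * d2[ii]
    }
    gr[ent$radial] <- gr[ent$radial] + weights["smooth"] * gd[-K]
    val <- val + weights["core"] * (cr[1] - 5)^2
    gr[ent$radial][1] <- gr[ent$radial][1] + weights["core"] * 2 * (cr[1] - 5)
    if (!is.null(ent$angular)) {
      ca <- pp$angular
      val <- val + weights["dir"] * (sum(ca^2) + sum(pp$ang1^2) + sum(pp$ang2^2))
      gr[ent$angular] <- gr[ent$angular] + weights["dir"] * 2 * ca[-K]
      gr[ent$ang1] <- gr[ent$ang1] + weights["dir"] * 2 * pp$ang1
      gr[ent$ang2] <- gr[ent$ang2] + weights["dir"] * 2 * pp$ang2
    }
  }
  val <- as.numeric(val)
  attr(val, "grad") <- gr
  val
}

# ---- training caches ----------------------------------------------------

# Geometry-only cache of one example: raw spline bases per interaction
# term, the rotamer prior, graph topology and native states.
build_train_cache <- function(example, params) {
  sys <- sc_system(example$chain, params, basis = TRUE)
  n <- length(sys$v)
  ns <- vapply(sys$v, length, integer(1))
  # prior-only part of v (subtract interaction contributions: rebuild)
  v0 <- vector("list", n)
  for (i in seq_len(n)) {
    tpp <- params$types[[sys$types[i]]]
    pt <- sys$prior_terms[[i]]
    if (!isTRUE(pt$dep)) v0[[i]] <- tpp$prior_indep
    else {
      v0[[i]] <- vapply(seq_len(ns[i]), function(a)
        .bilinear_periodic(tpp$rot_prior[a, , ], params$grid_centers,
                           sys$dihedrals$phi[i], sys$dihedrals$psi[i]),
        numeric(1))
    }
  }
  h <- RADIAL_SPACING; ha <- angular_spacing()
  raw_bases <- function(recs, pp, nrows) {
    K <- length(pp$radial)
    rs <- vapply(recs, function(t) if (is.null(t$r)) Inf else t$r, numeric(1))
    live <- is.finite(rs) & rs < pp$cutoff
    out <- list(live = live, K = K,
                Br = spline_basis(K, 0, h, pmin(rs, pp$cutoff), zero_above = TRUE))
    if (isTRUE(pp$directional)) {
      x1 <- vapply(recs, function(t) if (is.null(t$x1) || is.na(t$x1)) 0 else t$x1, numeric(1))
      x2 <- vapply(recs, function(t) if (is.null(t$x2) || is.na(t$x2)) 0 else t$x2, numeric(1))
      out$B1 <- spline_basis(ANGULAR_KNOTS, -1, ha, x1)
      out$B2 <- spline_basis(ANGULAR_KNOTS, -1, ha, x2)
      out$B1[!live, ] <- 0; out$B2[!live, ] <- 0
      out$Br[!live, ] <- 0
    } else out$Br[!live, ] <- 0
    out
  }
  scbb <- list()
  for (rec in sys$scbb_terms) {
    pp <- params$pair[[rec$key]]
    st <- sys$sites[[rec$site]]
    terms <- lapply(seq_len(rec$n_states), function(a) {
      # re-evaluate raw geometry for this term
      fe <- pair_energy_full(sys$beads[[rec$i]]$pos[a, ],
                             sys$beads[[rec$i]]$dir[a, ],
                             st$pos, st$dir, pp, kappa = 1, basis = TRUE)
      fe
    })
    rb <- raw_bases(terms, pp, rec$n_states)
    scbb[[length(scbb) + 1L]] <- list(i = rec$i, key = rec$key,
                                      kappa = st$kappa,
                                      directional = isTRUE(pp$directional),
                                      bases = rb)
  }
  edges <- sys$edges
  esc <- list()
  ne <- if (is.null(edges)) 0L else nrow(edges)
  for (e in seq_len(ne)) {
    key <- sys$edge_terms[[e]]$key
    pp <- params$pair[[key]]
    terms <- sys$edge_terms[[e]]$terms
    rb <- raw_bases(terms, pp, length(terms))
    esc[[e]] <- list(i = edges[e, 1], j = edges[e, 2], key = key,
                     directional = isTRUE(pp$directional), bases = rb)
  }
  list(n = n, ns = ns, native = example$native, v0 = v0,
       edges = edges, scbb = scbb, edge_cache = esc)
}

# Evaluate v and v_ij for a cache at the parameter values in `params`.
.cache_energies <- function(cache, params) {
  v <- lapply(cache$v0, identity)
  for (rec in cache$scbb) {
    pp <- params$pair[[rec$key]]
    val <- .term_values(rec$bases, pp, rec$directional) * rec$kappa
    v[[rec$i]] <- v[[rec$i]] + val
  }
  ne <- if (is.null(cache$edges)) 0L else nrow(cache$edges)
  v_ij <- vector("list", ne)
  for (e in seq_len(ne)) {
    ec <- cache$edge_cache[[e]]
    pp <- params$pair[[ec$key]]
    val <- .term_values(ec$bases, pp, ec$directional)
    v_ij[[e]] <- matrix(val, cache$ns[ec$i], cache$ns[ec$j])
  }
  list(v = v, v_ij = v_ij)
}

.term_values <- function(rb, pp, directional) {
  val <- as.numeric(rb$Br %*% pp$radial)
  if (directional) {
    a1 <- as.numeric(rb$B1 %*% exp(pp$ang1))
    a2 <- as.numeric(rb$B2 %*% exp(pp$ang2))
    va <- as.numeric(rb$Br %*% pp$angular)
    val <- val + as.numeric(rb$live) * a1 * a2 * va
  }
  val
}

# Accumulate d(sum w_t * value_t)/dtheta for one cached record into `gr`.
.term_grad_acc <- function(gr, ent, rb, pp, directional, w, kappa = 1) {
  if (is.null(ent)) return(gr)
  wk <- w * kappa
  K <- rb$K
  gradial <- as.numeric(crossprod(rb$Br, wk))
  gr[ent$radial] <- gr[ent$radial] + gradial[-K]
  if (directional && !is.null(ent$angular)) {
    a1 <- as.numeric(rb$B1 %*% exp(pp$ang1))
    a2 <- as.numeric(rb$B2 %*% exp(pp$ang2))
    va <- as.numeric(rb$Br %*% pp$angular)
    gang <- as.numeric(crossprod(rb$Br, wk * a1 * a2))
    gr[ent$angular] <- gr[ent$angular] + gang[-K]
    gr[ent$ang1] <- gr[ent$ang1] +
      exp(pp$ang1) * as.numeric(crossprod(rb$B1, wk * a2 * va))
    gr[ent$ang2] <- gr[ent$ang2] +
      exp(pp$ang2) * as.numeric(crossprod(rb$B2, wk * a1 * va))
  }
  gr
}

# E_gap and its parameter gradient for one cached example.
.cache_gap_grad <- function(cache, params, lay, lambda, tol, max_iter,
                            per = "protein", want_grad = TRUE, init = NULL) {
  en <- .cache_energies(cache, params)
  nat <- cache$native
  Vn <- sum(vapply(seq_len(cache$n), function(i) en$v[[i]][nat[i]], numeric(1)))
  ne <- if (is.null(cache$edges)) 0L else nrow(cache$edges)
  for (e in seq_len(ne))
    Vn <- Vn + en$v_ij[[e]][nat[cache$edges[e, 1]], nat[cache$edges[e, 2]]]
  ms <- solve_marginals(en$v, cache$edges, en$v_ij, lambda = lambda,
                        tol = tol, max_iter = max_iter, init = init)
  gap <- Vn - ms$G
  scale <- if (per == "residue") 1 / cache$n else 1
  if (!want_grad)
    return(list(gap = gap * scale, converged = ms$converged,
                state = ms$state))
  gr <- numeric(attr(lay, "n"))
  for (rec in cache$scbb) {
    ent <- lay[[rec$key]]
    if (is.null(ent)) next
    w <- -ms$p[[rec$i]]
    w[nat[rec$i]] <- w[nat[rec$i]] + 1
    pp <- params$pair[[rec$key]]
    gr <- .term_grad_acc(gr, ent, rec$bases, pp, rec$directional, w, rec$kappa)
  }
  for (e in seq_len(ne)) {
    ec <- cache$edge_cache[[e]]
    ent <- lay[[ec$key]]
    if (is.null(ent)) next
    w <- -as.numeric(ms$p_edges[[e]])
    k <- (nat[ec$j] - 1L) * cache$ns[ec$i] + nat[ec$i]
    w[k] <- w[k] + 1
    pp <- params$pair[[ec$key]]
    gr <- .term_grad_acc(gr, ent, ec$bases, pp, ec$directional, w, 1)
  }
  list(gap = gap * scale, grad = gr * scale, converged = ms$converged,
       state = ms$state)
}

#' Parametric gradient of the energy gap
#'
#' The envelope identity applied to the spline coefficients:
#' `dE_gap/dtheta = dV(native)/dtheta - sum_i E_{p_i}[dv_i/dtheta]
#' - sum_edges E_{p_ij}[dv_ij/dtheta]`.  Coefficients of residue-type
#' pairs absent from the example get exactly zero gradient.
#'
#' @inheritParams energy_gap
#' @param keys pair-block keys to differentiate (default: all).
#' @return numeric gradient in the [flatten_params()] layout.
#' @export
parameter_gradient <- function(example, params, keys = NULL,
                               lambda = 0.4, tol = 1e-3, max_iter = 1000L,
                               per = c("protein", "residue")) {
  per <- match.arg(per)
  cache <- build_train_cache(example, params)
  lay <- param_layout(params, keys)
  out <- .cache_gap_grad(cache, params, lay, lambda, tol, max_iter, per)
  out$grad
}

#' Adam optimizer configuration
#'
#' @param alpha,beta1,beta2,eps Adam scalars.
#' @param minibatch examples per step.
#' @param steps number of Adam steps.
#' @param seed RNG seed for minibatch sampling.
#' @param lambda,tol,max_iter belief-propagation controls during training.
#' @param per gap normalization, `"protein"` or `"residue"`.
#' @param reg_weights weights of the three regularization penalties.
#' @return list of settings.
#' @export
optimizer_config <- function(alpha = 0.03, beta1 = 0.90, beta2 = 0.96,
                             eps = 1e-6, minibatch = 256L, steps = 200L,
                             seed = 1L, lambda = 0.4, tol = 1e-3,
                             max_iter = 400L, per = "protein",
                             reg_weights = c(smooth = 1e-3, dir = 1e-3,
                                             core = 1e-3)) {
  list(alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps,
       minibatch = as.integer(minibatch), steps = as.integer(steps),
       seed = as.integer(seed), lambda = lambda, tol = tol,
       max_iter = as.integer(max_iter), per = per, reg_weights = reg_weights)
}

#' Train the spline potential by energy-gap minimization
#'
#' Adam updates on minibatches of the mean energy gap plus regularization.
#' Angular coefficients stay positive through the exponential transform in
#' their storage; under the repulsive-only restriction radial knots are
#' projected to be non-negative after each step.  Deterministic given the
#' seed in `config`.
#'
#' @param dataset list of [training_example()] objects.
#' @param params0 starting `parameter_set`.
#' @param config an [optimizer_config()].
#' @param keys pair-block keys to train (default: all).
#' @param caches optional precomputed caches from an earlier run on the
#'   same dataset/params (geometry only, safe to reuse).
#' @return list with trained `params`, the per-step `trace` data frame
#'   (loss, mean gap, regularization), and the final `theta`.
#' @export
train <- function(dataset, params0, config = optimizer_config(),
                  keys = NULL, caches = NULL) {
  if (!length(dataset)) stop("empty training dataset")
  if (is.null(caches))
    caches <- lapply(dataset, build_train_cache, params = params0)
  lay <- param_layout(params0, keys)
  np <- attr(lay, "n")
  theta <- flatten_params(params0, keys)
  params <- params0
  m <- numeric(np); vv <- numeric(np)
  bp_states <- vector("list", length(caches))   # warm starts across steps
  trace <- data.frame(step = integer(), loss = numeric(), egap = numeric(),
                      reg = numeric())
  .with_seed(config$seed, {
    for (step in seq_len(config$steps)) {
      take <- if (length(caches) <= config$minibatch) seq_along(caches)
      else sample.int(length(caches), config$minibatch)
      g <- numeric(np); gap <- 0
      for (k in take) {
        out <- .cache_gap_grad(caches[[k]], params, lay, config$lambda,
                               config$tol, config$max_iter, config$per,
                               init = bp_states[[k]])
        bp_states[[k]] <- out$state
        g <- g + out$grad
        gap <- gap + out$gap
      }
      g <- g / length(take); gap <- gap / length(take)
      reg <- regularization(params, config$reg_weights, keys)
      g <- g + attr(reg, "grad")
      loss <- gap + as.numeric(reg)
      if (!is.finite(loss)) stop("divergent training loss at step ", step)
      m <- config$beta1 * m + (1 - config$beta1) * g
      vv <- config$beta2 * vv + (1 - config$beta2) * g^2
      mh <- m / (1 - config$beta1^step)
      vh <- vv / (1 - config$beta2^step)
      theta <- theta - config$alpha * mh / (sqrt(vh) + config$eps)
      if (isTRUE(params$config$repulsive_only)) {
        for (ent in lay) theta[ent$radial] <- pmax(theta[ent$radial], 0)
      }
      params <- unflatten_params(params, theta, lay)
      trace <- rbind(trace, data.frame(step = step, loss = loss,
                                        egap = gap, reg = as.numeric(reg)))
    }
  })
  list(params = params, trace = trace, theta = theta)
}

#' Mean held-out energy gap of a dataset
#'
#' @inheritParams train
#' @param params a `parameter_set`.
#' @param per normalization, as in [energy_gap()].
#' @param solver `"bp"` or `"exact"`.
#' @return mean energy gap in kT.
#' @export
mean_energy_gap <- function(dataset, params, per = "protein", solver = "bp",
                            lambda = 0.4, tol = 1e-3, max_iter = 1000L) {
  mean(vapply(dataset, energy_gap, numeric(1), params = params,
              solver = solver, per = per, lambda = lambda, tol = tol,
              max_iter = max_iter))
}

#' chi1 rotamer prediction accuracy
#'
#' Fraction of residues whose most probable coarse state maps to the native
#' chi1 bin (the coarse-to-chi1 map is unambiguous by construction of the
#' partition).  Alanine, glycine and proline are excluded from numerator
#' and denominator; with no eligible residues the result is NaN with
#' attribute `n = 0`.
#'
#' @param dataset list of [training_example()] objects.
#' @param params a `parameter_set`.
#' @param prior_only if TRUE, predict from the rotamer prior alone (the
#'   no-interaction baseline).
#' @inheritParams energy_gap
#' @return accuracy in \code{[0, 1]} with attribute `"n"` (eligible
#'   residues).
#' @export
chi1_accuracy <- function(dataset, params, prior_only = FALSE,
                          lambda = 0.4, tol = 1e-3, max_iter = 1000L) {
  use_params <- if (prior_only) ablation_preset(params, "no_interactions")
  else params
  hits <- 0L; total <- 0L
  excl <- c("ALA", "GLY", "PRO")
  for (ex in dataset) {
    ms <- side_chain_marginals(ex$chain, use_params, lambda = lambda,
                               tol = tol, max_iter = max_iter)
    for (i in seq_along(ex$native)) {
      tp <- ex$chain$residues[i]
      if (tp %in% excl) next
      chi1 <- use_params$types[[tp]]$chi1_of_state
      pred <- which.max(ms$p[[i]])
      total <- total + 1L
      if (identical(chi1[pred], chi1[ex$native[i]])) hits <- hits + 1L
    }
  }
  acc <- if (total == 0L) NaN else hits / total
  attr(acc, "n") <- total
  acc
}

#' RANSAC filter for non-globular chains
#'
#' Fits the linear relationship between log10(N_res) and log10(R_g) by
#' RANSAC and drops outliers — chains whose radius of gyration departs from
#' the globular power-law trend.
#'
#' @param chains list of [backbone_chain()].
#' @param threshold inlier threshold on the |log10 R_g| residual.
#' @param trials number of RANSAC draws.
#' @param seed RNG seed.
#' @param min_chains below this the input is returned untouched with a
#'   warning.
#' @return list with `chains` (retained), `inliers` (logical), and `fit`
#'   (intercept/slope of the consensus line).
#' @export
filter_nonglobular <- function(chains, threshold = 0.1, trials = 1000L,
                               seed = 1L, min_chains = 10L) {
  n <- length(chains)
  if (n < min_chains) {
    warning("fewer than ", min_chains, " chains; RANSAC filter skipped")
    return(list(chains = chains, inliers = rep(TRUE, n), fit = NULL))
  }
  x <- log10(vapply(chains, function(ch) length(ch$residues), numeric(1)))
  y <- log10(vapply(chains, radius_of_gyration, numeric(1)))
  .with_seed(seed, {
    best <- NULL
    for (t in seq_len(trials)) {
      k <- sample.int(n, 2)
      if (abs(x[k[1]] - x[k[2]]) < 1e-12) next
      b <- (y[k[2]] - y[k[1]]) / (x[k[2]] - x[k[1]])
      a <- y[k[1]] - b * x[k[1]]
      res <- abs(y - (a + b * x))
      inl <- res <= threshold
      sc <- sum(inl)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && sum(res[inl]^2) < best$sse)) {
        best <- list(score = sc, sse = sum(res[inl]^2), inliers = inl)
      }
    }
    fit <- stats::lm.fit(cbind(1, x[best$inliers]), y[best$inliers])
    co <- fit$coefficients
    inl <- abs(y - (co[1] + co[2] * x)) <= threshold
    list(chains = chains[inl], inliers = inl,
         fit = c(intercept = unname(co[1]), slope = unname(co[2])))
  })
}
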