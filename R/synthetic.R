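# Deterministic synthetic generators.  They stand in for the external
# backbone-dependent rotamer library and curated PDB training sets so that
# every stage of the pipeline — coarse-graining, energy assembly, belief
# propagation, training, dynamics — runs and is testable offline.  All
# generators are pure functions of (seed, arguments).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic fine rotamer library
#'
#' Fine states on a chi1 x chi2 (x higher-chi) grid with smoothly
#' (phi, psi)-dependent probabilities (softmax of low-order Fourier fields)
#' and geometrically plausible atom positions: a CB-like atom at ~1.5 A
#' from the local origin shared within each chi1 bin, and a CG-like atom at
#' ~2.5-3.5 A resolving chi2, so that variance-minimizing partitions have
#' real structure to find.
#'
#' @param seed integer seed.
#' @param types residue type names (three-letter codes).
#' @param n_chi1,n_chi2 rotamer bins per type (recycled); residues named
#'   ALA/GLY/PRO always get a single state.
#' @param n_higher extra non-chi1/chi2 states per (chi1, chi2) bin.
#' @param spacing_deg (phi, psi) grid spacing in degrees.
#' @return a [fine_rotamer_library()].
#' @export
gen_rotamer_library <- function(seed, types = c("SER", "VAL", "LEU"),
                                n_chi1 = 3L, n_chi2 = 1L, n_higher = 1L,
                                spacing_deg = 10) {
  n_chi1 <- rep_len(n_chi1, length(types))
  n_chi2 <- rep_len(n_chi2, length(types))
  centers <- rama_grid_centers(spacing_deg)
  G <- length(centers)
  cphi <- outer(cos(centers), rep(1, G))
  sphi <- outer(sin(centers), rep(1, G))
  cpsi <- outer(rep(1, G), cos(centers))
  spsi <- outer(rep(1, G), sin(centers))
  .with_seed(seed, {
    tl <- list()
    for (t in seq_along(types)) {
      nm <- types[t]
      n1 <- if (nm %in% c("ALA", "GLY", "PRO")) 1L else n_chi1[t]
      n2 <- if (n1 == 1L) 1L else n_chi2[t]
      nh <- if (n1 == 1L) 1L else n_higher
      grid <- expand.grid(h = seq_len(nh), c2 = seq_len(n2), c1 = seq_len(n1))
      nf <- nrow(grid)
      logw <- array(0, c(nf, G, G))
      for (f in seq_len(nf)) {
        b <- stats::rnorm(5, sd = c(1, 0.6, 0.6, 0.6, 0.6))
        logw[f, , ] <- b[1] + b[2] * cphi + b[3] * sphi + b[4] * cpsi + b[5] * spsi
      }
      mx <- apply(logw, c(2, 3), max)
      w <- exp(sweep(logw, c(2, 3), mx))
      prob <- sweep(w, c(2, 3), apply(w, c(2, 3), sum), "/")
      na <- if (n1 == 1L) 1L else 2L
      atoms <- array(0, c(nf, na, 3))
      elev <- 0.9
      for (f in seq_len(nf)) {
        c1 <- grid$c1[f]; c2 <- grid$c2[f]; hh <- grid$h[f]
        az1 <- 2 * pi * (c1 - 0.5) / n1
        cb <- 1.5 * c(cos(az1) * cos(elev), sin(az1) * cos(elev), sin(elev))
        atoms[f, 1, ] <- cb
        if (na >= 2) {
          az2 <- az1 + 0.8 * (c2 - (n2 + 1) / 2) / max(1, n2)
          el2 <- elev - 0.5 + 0.08 * (hh - (nh + 1) / 2)
          atoms[f, 2, ] <- cb + 1.6 * c(cos(az2) * cos(el2),
                                        sin(az2) * cos(el2), sin(el2))
        }
      }
      tl[[nm]] <- list(chi1_bin = grid$c1, chi2_bin = grid$c2,
                       chi_higher = grid$h, prob = prob, atoms = atoms,
                       n_chi1 = n1, n_chi2 = n2)
    }
    fine_rotamer_library(tl, centers)
  })
}

#' Synthetic Ramachandran density
#'
#' A smooth two-basin mixture (helical basin near (-57, -47) degrees,
#' extended basin near (-135, 135) degrees) with periodic wrapping,
#' normalized on the grid.
#'
#' @param spacing_deg grid spacing in degrees.
#' @param w_helix weight of the helical basin.
#' @return a [rama_density()].
#' @export
synthetic_rama_density <- function(spacing_deg = 10, w_helix = 0.45) {
  centers <- rama_grid_centers(spacing_deg)
  wrap <- function(x) atan2(sin(x), cos(x))
  basin <- function(phi0, psi0, s) {
    dphi <- wrap(outer(centers - phi0, rep(0, length(centers)), "+"))
    dpsi <- wrap(outer(rep(0, length(centers)), centers - psi0, "+"))
    exp(-(dphi^2 + dpsi^2) / (2 * s^2))
  }
  d2r <- pi / 180
  dens <- w_helix * basin(-57 * d2r, -47 * d2r, 25 * d2r) +
    (1 - w_helix) * basin(-135 * d2r, 135 * d2r, 30 * d2r)
  rama_density(dens, centers)
}

#' Synthetic backbone chain at ideal covalent geometry
#'
#' Builds an N/CA/C trace by successive internal-coordinate placement at
#' the ideal bond lengths (N-CA 1.453, CA-C 1.526, C-N 1.300 A) and angles
#' (109.5 deg at CA, 120 deg at C and N), with (phi, psi) set by the
#' requested topology plus optional Gaussian noise.
#'
#' @param seed integer seed (sequence and noise).
#' @param n_residues chain length.
#' @param topology `"helix"` (-57, -47), `"extended"` (-135, 135) or
#'   `"random"` (basin mixture per residue).
#' @param types residue types to draw the sequence from.
#' @param noise_deg dihedral noise standard deviation in degrees.
#' @return a [backbone_chain()].
#' @export
gen_toy_protein <- function(seed, n_residues, topology = c("helix", "extended", "random"),
                            types = c("SER", "VAL", "LEU"), noise_deg = 0) {
  topology <- match.arg(topology)
  d2r <- pi / 180
  .with_seed(seed, {
    seqn <- sample(types, n_residues, replace = TRUE)
    base <- switch(topology,
      helix = cbind(rep(-57, n_residues), rep(-47, n_residues)),
      extended = cbind(rep(-135, n_residues), rep(135, n_residues)),
      random = {
        pick <- sample(c(TRUE, FALSE), n_residues, replace = TRUE)
        cbind(ifelse(pick, -57, -135), ifelse(pick, -47, 135))
      })
    di <- base + matrix(stats::rnorm(2 * n_residues, sd = noise_deg), ncol = 2)
    phi <- di[, 1] * d2r; psi <- di[, 2] * d2r
    N <- matrix(0, n_residues, 3); CA <- N; C <- N
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(1.453, 0, 0)
    ang_ca <- 109.5 * d2r
    C[1, ] <- CA[1, ] + 1.526 * c(-cos(ang_ca), sin(ang_ca), 0)
    for (i in seq_len(n_residues - 1)) {
      N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.300, 120 * d2r, psi[i])
      CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], 1.453, 120 * d2r, pi)
      C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], 1.526, ang_ca,
                               phi[i + 1])
    }
    backbone_chain(seqn, N, CA, C)
  })
}

# Enumerate the joint distribution of a small discrete system.
.enumerate_joint <- function(v, edges, v_ij, limit = 2e6) {
  ns <- vapply(v, length, integer(1))
  S <- prod(ns)
  if (S > limit) stop("state space too large for exact sampling (", S, ")")
  n <- length(v)
  stride <- cumprod(c(1, ns[-n]))
  ids <- 0:(S - 1)
  si <- matrix(0L, S, n)
  for (k in seq_len(n)) si[, k] <- (ids %/% stride[k]) %% ns[k] + 1L
  E <- numeric(S)
  for (k in seq_len(n)) E <- E + v[[k]][si[, k]]
  ne <- if (is.null(edges)) 0L else nrow(edges)
  for (e in seq_len(ne))
    E <- E + v_ij[[e]][cbind(si[, edges[e, 1]], si[, edges[e, 2]])]
  lw <- -E
  lw <- lw - max(lw)
  list(states = si, prob = exp(lw) / sum(exp(lw)))
}

#' A training example: backbone plus native coarse states
#'
#' @param chain a [backbone_chain()].
#' @param native integer vector of native coarse-state indices per residue.
#' @param params optional `parameter_set` used to validate state ranges.
#' @return object of class `training_example`.
#' @export
training_example <- function(chain, native, params = NULL) {
  stopifnot(length(native) == length(chain$residues))
  if (!is.null(params)) {
    for (i in seq_along(native)) {
      ns <- params$types[[chain$residues[i]]]$n_states
      if (native[i] < 1 || native[i] > ns)
        stop("native state out of range at residue ", i)
    }
  }
  structure(list(chain = chain, native = as.integer(native)),
            class = "training_example")
}

#' Exact-Boltzmann synthetic training set from a planted potential
#'
#' For each chain the discrete side-chain system is built under the
#' planted parameters and native states are drawn exactly from the joint
#' Boltzmann distribution by complete enumeration (no MCMC), so any
#' failure of parameter recovery implicates the trainer, not the sampler.
#'
#' @param params the planted `parameter_set`.
#' @param chains list of [backbone_chain()] (small: enumerable state
#'   spaces).
#' @param seed integer seed.
#' @return list of [training_example()] objects.
#' @export
gen_training_set <- function(params, chains, seed) {
  .with_seed(seed, {
    lapply(chains, function(ch) {
      sys <- sc_system(ch, params)
      ej <- .enumerate_joint(sys$v, sys$edges, sys$v_ij)
      k <- sample.int(nrow(ej$states), 1, prob = ej$prob)
      training_example(ch, ej$states[k, ], params)
    })
  })
}

#' Random loopy discrete field for convergence studies
#'
#' A geometric random graph (points in a box, edges within a radius chosen
#' for mean degree ~6) with standard-normal 1-residue energies and
#' normal pair energies of unit scale — the magnitudes typical of
#' thermalized side-chain problems in kT units.
#'
#' @param seed integer seed.
#' @param n number of residues.
#' @param states states per residue.
#' @param coupling standard deviation of the pair energies (kT).
#' @return list with `v`, `edges`, `v_ij`.
#' @export
gen_random_field <- function(seed, n = 50L, states = 3L, coupling = 1) {
  .with_seed(seed, {
    L <- (n / 0.01)^(1 / 3)          # density 0.01 per cubic unit
    r <- (6 / (0.01 * 4 / 3 * pi))^(1 / 3)
    P <- matrix(stats::runif(3 * n, 0, L), n, 3)
    D <- as.matrix(stats::dist(P))
    edges <- which(upper.tri(D) & D < r, arr.ind = TRUE)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    v <- lapply(seq_len(n), function(i) stats::rnorm(states))
    v_ij <- lapply(seq_len(nrow(edges)), function(e)
      matrix(stats::rnorm(states * states, sd = coupling), states, states))
    list(v = v, edges = unname(edges), v_ij = v_ij)
  })
}
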