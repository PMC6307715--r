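# Assembly of the discrete side-chain problem for a fixed backbone: derived
# O/H atoms, per-residue frames and oriented beads, hydrogen-bond gating of
# the side chain-backbone terms, the interaction graph, and the 1-residue
# vectors v_i / 2-residue matrices v_ij consumed by belief propagation.
# With `grad = TRUE` every term also carries the pieces needed to assemble
# the analytic backbone gradient of the free energy via the envelope
# identity; with `basis = TRUE` it carries the spline-coefficient bases
# used by maximum-likelihood training.

# Periodic bilinear interpolation on a square grid of cell centers.
.bilinear_periodic <- function(E, centers, x, y, grad = FALSE) {
  G <- length(centers)
  delta <- centers[2] - centers[1]
  tx <- (x - centers[1]) / delta; ty <- (y - centers[1]) / delta
  ix <- floor(tx); iy <- floor(ty)
  fx <- tx - ix; fy <- ty - iy
  i1 <- (ix %% G) + 1L; i2 <- (i1 %% G) + 1L
  j1 <- (iy %% G) + 1L; j2 <- (j1 %% G) + 1L
  v <- (1 - fx) * (1 - fy) * E[i1, j1] + fx * (1 - fy) * E[i2, j1] +
    (1 - fx) * fy * E[i1, j2] + fx * fy * E[i2, j2]
  if (!grad) return(v)
  dx <- ((E[i2, j1] - E[i1, j1]) * (1 - fy) +
           (E[i2, j2] - E[i1, j2]) * fy) / delta
  dy <- ((E[i1, j2] - E[i1, j1]) * (1 - fx) +
           (E[i2, j2] - E[i2, j1]) * fx) / delta
  list(value = v, dx = dx, dy = dy)
}

# Backbone-backbone hydrogen bonds: pair confidences, per-site aggregated
# scores, and (optionally) sparse gradients in the flat backbone
# coordinates.
compute_hbonds <- function(chain, derived, dj = NULL,
                           criteria = default_hbond_criteria(),
                           grad = FALSE) {
  n <- length(chain$residues)
  pairs <- list()
  for (i in seq_len(n)) {          # donor N_i-H_i
    if (any(!is.finite(derived$H[i, ]))) next
    for (j in seq_len(n)) {        # acceptor O_j=C_j
      if (abs(i - j) < 2) next
      if (any(!is.finite(derived$O[j, ]))) next
      r2 <- sum((derived$H[i, ] - derived$O[j, ])^2)
      if (r2 >= criteria$r_off^2) next
      res <- hbond_confidence(derived$H[i, ], derived$O[j, ],
                              chain$N[i, ], chain$C[j, ], criteria,
                              grad = grad)
      f <- if (grad) res$value else res
      if (f <= 0) next
      comps <- NULL
      if (grad) {
        comps <- list(
          list(idx = dj[[i]]$H$idx, g = as.numeric(res$dH %*% dj[[i]]$H$J)),
          list(idx = dj[[j]]$O$idx, g = as.numeric(res$dO %*% dj[[j]]$O$J)),
          list(idx = atom_cidx(i, "N"), g = res$dN),
          list(idx = atom_cidx(j, "C"), g = res$dC))
      }
      pairs[[length(pairs) + 1L]] <- list(donor = i, acceptor = j, f = f,
                                          comps = comps)
    }
  }
  f_H <- numeric(n); f_O <- numeric(n)
  df_H <- vector("list", n); df_O <- vector("list", n)
  agg <- function(idxs) {
    fs <- vapply(pairs[idxs], function(p) p$f, numeric(1))
    P <- prod(1 - fs)
    val <- 1 - P
    comps <- NULL
    if (grad) {
      comps <- list()
      for (k in seq_along(idxs)) {
        scale <- P / max(1 - fs[k], 1e-12)
        for (cc in pairs[[idxs[k]]]$comps)
          comps[[length(comps) + 1L]] <- list(idx = cc$idx, g = scale * cc$g)
      }
    }
    list(value = val, comps = comps)
  }
  for (i in seq_len(n)) {
    di <- which(vapply(pairs, function(p) p$donor == i, TRUE))
    if (length(di)) { a <- agg(di); f_H[i] <- a$value; df_H[[i]] <- a$comps }
    ai <- which(vapply(pairs, function(p) p$acceptor == i, TRUE))
    if (length(ai)) { a <- agg(ai); f_O[i] <- a$value; df_O[[i]] <- a$comps }
  }
  list(pairs = pairs, f_H = f_H, f_O = f_O, df_H = df_H, df_O = df_O)
}

#' Full side-chain evaluation context for one backbone configuration
#'
#' Builds everything the engine needs for a fixed backbone: derived O/H
#' atoms, residue frames, oriented beads, hydrogen-bond gating, the
#' interaction graph and the discrete energies.  With `grad = TRUE` each
#' term carries the pieces of the analytic backbone gradient; with
#' `basis = TRUE` the spline-coefficient bases used in training.
#'
#' @param chain a [backbone_chain()].
#' @param params a `parameter_set`.
#' @param grad,basis what derivative information to attach.
#' @return an `sc_system` object (see [build_local_energies()] for the
#'   simplified surface).
#' @export
sc_system <- function(chain, params, grad = FALSE, basis = FALSE) {
  cfg <- params$config
  n <- length(chain$residues)
  types <- chain$residues
  for (tp in unique(types))
    if (is.null(params$types[[tp]]))
      stop("no coarse states for residue type ", tp)
  dih <- chain_dihedrals(chain)
  derived <- place_peptide_atoms(chain, params$geometry)
  dj <- if (grad) derived_atom_jacobians(chain, params$geometry) else NULL
  hb <- compute_hbonds(chain, derived, dj, params$hbond, grad = grad)

  frames <- vector("list", n)
  beads <- vector("list", n)
  Jpos <- vector("list", n); Jdir <- vector("list", n)
  ncac_pos <- vector("list", n); ncac_J <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- residue_frame(chain$N[i, ], chain$CA[i, ], chain$C[i, ],
                        params$geometry$reference_ncac)
    frames[[i]] <- fr
    tpp <- params$types[[types[i]]]
    ns <- tpp$n_states
    pos <- tpp$bead_pos %*% t(fr$rotation)
    pos <- sweep(pos, 2, fr$translation, "+")
    dir <- tpp$bead_dir %*% t(fr$rotation)
    beads[[i]] <- list(pos = pos, dir = dir, n_states = ns)
    ncac_pos[[i]] <- sweep(params$backbone_beads %*% t(fr$rotation), 2,
                           fr$translation, "+")
    if (grad) {
      fd <- frame_differential(fr)
      om <- vector("list", 9); dt <- vector("list", 9)
      for (m in 1:3) for (d in 1:3) {
        e <- numeric(3); e[d] <- 1
        pr <- fd(m, e)
        om[[(m - 1) * 3 + d]] <- pr$omega
        dt[[(m - 1) * 3 + d]] <- pr$dt
      }
      R <- fr$rotation
      Jp <- vector("list", ns); Jd <- vector("list", ns)
      for (a in seq_len(ns)) {
        Jpa <- matrix(0, 3, 9); Jda <- matrix(0, 3, 9)
        for (k in 1:9) {
          Jpa[, k] <- R %*% cross3(om[[k]], tpp$bead_pos[a, ]) + dt[[k]]
          Jda[, k] <- R %*% cross3(om[[k]], tpp$bead_dir[a, ])
        }
        Jp[[a]] <- Jpa; Jd[[a]] <- Jda
      }
      Jpos[[i]] <- Jp; Jdir[[i]] <- Jd
      Jn <- vector("list", 3)
      for (b in 1:3) {
        Jb <- matrix(0, 3, 9)
        for (k in 1:9)
          Jb[, k] <- R %*% cross3(om[[k]], params$backbone_beads[b, ]) + dt[[k]]
        Jn[[b]] <- Jb
      }
      ncac_J[[i]] <- Jn
    }
  }

  # --- backbone interaction sites --------------------------------------
  sites <- list()
  res_span <- function(i) (i - 1L) * 9L + 1:9
  for (j in seq_len(n)) {
    if (isTRUE(cfg$use_HO) && all(is.finite(derived$O[j, ]))) {
      dir <- unit3(derived$O[j, ] - chain$C[j, ])
      jac <- jac_dir <- dk <- NULL
      if (grad) {
        jac <- list(list(idx = dj[[j]]$O$idx, J = dj[[j]]$O$J))
        Dd <- d_unit(derived$O[j, ] - chain$C[j, ])
        jac_dir <- list(list(idx = dj[[j]]$O$idx, J = Dd %*% dj[[j]]$O$J),
                        list(idx = atom_cidx(j, "C"), J = -Dd))
        if (!is.null(hb$df_O[[j]]))
          dk <- lapply(hb$df_O[[j]], function(cc)
            list(idx = cc$idx, g = -cc$g))   # kappa = 1 - f
      }
      sites[[length(sites) + 1L]] <- list(
        owner = j, class = "O", pos = derived$O[j, ], dir = dir,
        kappa = 1 - hb$f_O[j], jac = jac, jac_dir = jac_dir, dkappa = dk)
    }
    if (isTRUE(cfg$use_HO) && all(is.finite(derived$H[j, ]))) {
      dir <- unit3(derived$H[j, ] - chain$N[j, ])
      jac <- jac_dir <- dk <- NULL
      if (grad) {
        jac <- list(list(idx = dj[[j]]$H$idx, J = dj[[j]]$H$J))
        Dd <- d_unit(derived$H[j, ] - chain$N[j, ])
        jac_dir <- list(list(idx = dj[[j]]$H$idx, J = Dd %*% dj[[j]]$H$J),
                        list(idx = atom_cidx(j, "N"), J = -Dd))
        if (!is.null(hb$df_H[[j]]))
          dk <- lapply(hb$df_H[[j]], function(cc)
            list(idx = cc$idx, g = -cc$g))
      }
      sites[[length(sites) + 1L]] <- list(
        owner = j, class = "H", pos = derived$H[j, ], dir = dir,
        kappa = 1 - hb$f_H[j], jac = jac, jac_dir = jac_dir, dkappa = dk)
    }
    if (isTRUE(cfg$use_NCAC)) {
      for (b in 1:3) {
        jac <- if (grad) list(list(idx = res_span(j), J = ncac_J[[j]][[b]]))
        sites[[length(sites) + 1L]] <- list(
          owner = j, class = "NCAC", pos = ncac_pos[[j]][b, ], dir = NULL,
          kappa = 1, jac = jac, jac_dir = NULL, dkappa = NULL)
      }
    }
  }

  # --- interaction graph -----------------------------------------------
  site_df <- if (length(sites))
    data.frame(residue = vapply(sites, function(s) s$owner, integer(1)),
               x = vapply(sites, function(s) s$pos[1], numeric(1)),
               y = vapply(sites, function(s) s$pos[2], numeric(1)),
               z = vapply(sites, function(s) s$pos[3], numeric(1)))
  else NULL
  gr <- build_graph(lapply(beads, `[[`, "pos"), site_df,
                    cutoff_scsc = cfg$cutoff_scsc,
                    cutoff_scbb = cfg$cutoff_scbb,
                    min_seq_sep = cfg$min_seq_sep,
                    include_self = isTRUE(cfg$include_intra_backbone))
  edges <- gr$edges
  if (!isTRUE(cfg$sc_sc)) edges <- matrix(integer(), 0, 2)
  scbb_pairs <- gr$scbb
  if (!isTRUE(cfg$sc_bb) || is.null(scbb_pairs))
    scbb_pairs <- data.frame(residue = integer(), site = integer())

  # --- 1-residue energies ----------------------------------------------
  v <- vector("list", n)
  prior_terms <- vector("list", n)
  for (i in seq_len(n)) {
    tpp <- params$types[[types[i]]]
    ns <- tpp$n_states
    if (isTRUE(cfg$phi_psi_independent) ||
        is.na(dih$phi[i]) || is.na(dih$psi[i])) {
      v[[i]] <- tpp$prior_indep
      prior_terms[[i]] <- list(dep = FALSE)
    } else {
      E <- numeric(ns); dphi <- numeric(ns); dpsi <- numeric(ns)
      for (a in seq_len(ns)) {
        bi <- .bilinear_periodic(tpp$rot_prior[a, , ], params$grid_centers,
                                 dih$phi[i], dih$psi[i], grad = grad)
        if (grad) { E[a] <- bi$value; dphi[a] <- bi$dx; dpsi[a] <- bi$dy }
        else E[a] <- bi
      }
      v[[i]] <- E
      pt <- list(dep = TRUE, dphi = dphi, dpsi = dpsi)
      if (grad) {
        pt$gphi <- dihedral_gradient(chain$C[i - 1, ], chain$N[i, ],
                                     chain$CA[i, ], chain$C[i, ])
        pt$idx_phi <- c(atom_cidx(i - 1, "C"), atom_cidx(i, "N"),
                        atom_cidx(i, "CA"), atom_cidx(i, "C"))
        pt$gpsi <- dihedral_gradient(chain$N[i, ], chain$CA[i, ],
                                     chain$C[i, ], chain$N[i + 1, ])
        pt$idx_psi <- c(atom_cidx(i, "N"), atom_cidx(i, "CA"),
                        atom_cidx(i, "C"), atom_cidx(i + 1, "N"))
      }
      prior_terms[[i]] <- pt
    }
  }

  scbb_terms <- list()
  if (nrow(scbb_pairs)) {
    for (r in seq_len(nrow(scbb_pairs))) {
      i <- scbb_pairs$residue[r]; s <- scbb_pairs$site[r]
      st <- sites[[s]]
      key <- bb_pair_key(types[i], st$class)
      pp <- params$pair[[key]]
      ns <- beads[[i]]$n_states
      rec <- list(i = i, site = s, key = key, n_states = ns,
                  unit = numeric(ns))
      if (grad) {
        rec$dy1 <- matrix(0, ns, 3); rec$dn1 <- matrix(0, ns, 3)
        rec$dy2 <- matrix(0, ns, 3); rec$dn2 <- matrix(0, ns, 3)
      }
      if (basis) {
        K <- length(pp$radial)
        rec$b_radial <- matrix(0, ns, K)
        if (isTRUE(pp$directional)) {
          rec$b_angular <- matrix(0, ns, K)
          rec$b_ang1 <- matrix(0, ns, ANGULAR_KNOTS)
          rec$b_ang2 <- matrix(0, ns, ANGULAR_KNOTS)
        }
      }
      for (a in seq_len(ns)) {
        fe <- pair_energy_full(beads[[i]]$pos[a, ], beads[[i]]$dir[a, ],
                               st$pos, st$dir, pp, kappa = st$kappa,
                               grad = grad, basis = basis)
        v[[i]][a] <- v[[i]][a] + fe$value
        rec$unit[a] <- fe$unit_value
        if (grad) {
          rec$dy1[a, ] <- fe$dy1; rec$dn1[a, ] <- fe$dn1
          rec$dy2[a, ] <- fe$dy2; rec$dn2[a, ] <- fe$dn2
        }
        if (basis) {
          rec$b_radial[a, ] <- fe$b_radial
          if (isTRUE(pp$directional)) {
            rec$b_angular[a, ] <- fe$b_angular
            rec$b_ang1[a, ] <- fe$b_ang1
            rec$b_ang2[a, ] <- fe$b_ang2
          }
        }
      }
      scbb_terms[[length(scbb_terms) + 1L]] <- rec
    }
  }

  # --- 2-residue energies ----------------------------------------------
  ne <- nrow(edges)
  v_ij <- vector("list", ne)
  edge_terms <- vector("list", ne)
  if (ne) {
    for (e in seq_len(ne)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      flip <- types[j] < types[i]       # first directional slot = sorted-first type
      key <- sc_pair_key(types[i], types[j])
      pp <- params$pair[[key]]
      ni <- beads[[i]]$n_states; nj <- beads[[j]]$n_states
      V <- matrix(0, ni, nj)
      terms <- if (grad || basis) vector("list", ni * nj) else NULL
      for (a in seq_len(ni)) for (b in seq_len(nj)) {
        if (!flip) {
          fe <- pair_energy_full(beads[[i]]$pos[a, ], beads[[i]]$dir[a, ],
                                 beads[[j]]$pos[b, ], beads[[j]]$dir[b, ],
                                 pp, grad = grad, basis = basis)
        } else {
          fe <- pair_energy_full(beads[[j]]$pos[b, ], beads[[j]]$dir[b, ],
                                 beads[[i]]$pos[a, ], beads[[i]]$dir[a, ],
                                 pp, grad = grad, basis = basis)
          if (grad) {
            tmp <- fe$dy1; fe$dy1 <- fe$dy2; fe$dy2 <- tmp
            tmp <- fe$dn1; fe$dn1 <- fe$dn2; fe$dn2 <- tmp
          }
        }
        V[a, b] <- fe$value
        if (grad || basis) terms[[(b - 1L) * ni + a]] <- fe
      }
      v_ij[[e]] <- V
      edge_terms[[e]] <- list(key = key, terms = terms)
    }
  }

  structure(list(chain = chain, params = params, types = types,
                 dihedrals = dih, derived = derived, derived_jac = dj,
                 hbonds = hb, frames = frames, beads = beads,
                 Jpos = Jpos, Jdir = Jdir, sites = sites,
                 edges = edges, v = v, v_ij = v_ij,
                 prior_terms = prior_terms, scbb_terms = scbb_terms,
                 edge_terms = edge_terms, grad = grad, basis = basis),
            class = "sc_system")
}

#' Assemble the discrete side-chain energies for a fixed backbone
#'
#' Computes the 1-residue energy vectors (rotamer prior plus hydrogen-bond
#' gated side chain-backbone terms) and the 2-residue side chain-side chain
#' energy matrices on the dynamically built interaction graph.
#'
#' @param chain a [backbone_chain()].
#' @param params a `parameter_set`.
#' @return list with `v` (energy vectors), `edges`, `v_ij` (matrices),
#'   plus the derived atoms, hydrogen-bond scores, beads and sites used.
#' @export
build_local_energies <- function(chain, params) {
  sys <- sc_system(chain, params)
  list(v = sys$v, edges = sys$edges, v_ij = sys$v_ij,
       derived = sys$derived, hbonds = sys$hbonds[c("f_H", "f_O")],
       beads = sys$beads, system = sys)
}

#' Side-chain marginals and free energy for a backbone
#'
#' Builds the interaction system and runs damped belief propagation.
#'
#' @inheritParams build_local_energies
#' @inheritParams solve_marginals
#' @param system optional prebuilt `sc_system` (for reuse).
#' @return a `marginal_set` with the `sc_system` attached as `$system`.
#' @export
side_chain_marginals <- function(chain, params, lambda = 0.4, tol = 1e-3,
                                 max_iter = 1000L, init = NULL,
                                 system = NULL) {
  sys <- if (is.null(system)) sc_system(chain, params) else system
  ms <- solve_marginals(sys$v, sys$edges, sys$v_ij, lambda = lambda,
                        tol = tol, max_iter = max_iter, init = init)
  ms$system <- sys
  ms
}

#' Analytic backbone gradient of the side-chain free energy
#'
#' Because the marginals minimize the Bethe free energy, its backbone
#' derivative is the marginal-weighted expectation of the energy
#' derivatives; the entropy contributes nothing.  All derived-site
#' contributions (O, H, beads, hydrogen-bond gating) are pulled back onto
#' the N/CA/C atoms through their analytic placement Jacobians.
#'
#' @param chain a [backbone_chain()].
#' @param marginals a converged `marginal_set` for this backbone.
#' @param params a `parameter_set`.
#' @param system optional `sc_system` built with `grad = TRUE`.
#' @return list with `gradient` and `forces` (= -gradient), both
#'   `3 n_res x 3` matrices over atoms in (N, CA, C) residue order, in
#'   kT/Angstrom, and `converged` echoing the marginals.
#' @export
side_chain_forces <- function(chain, marginals, params, system = NULL) {
  sys <- if (!is.null(system) && isTRUE(system$grad)) system
  else sc_system(chain, params, grad = TRUE)
  if (!isTRUE(marginals$converged))
    warning("marginals not converged; side-chain forces are approximate")
  n <- length(chain$residues)
  g <- numeric(9L * n)
  p <- marginals$p
  res_span <- function(i) (i - 1L) * 9L + 1:9
  # rotamer prior via phi/psi
  for (i in seq_len(n)) {
    pt <- sys$prior_terms[[i]]
    if (!isTRUE(pt$dep)) next
    wphi <- sum(p[[i]] * pt$dphi)
    wpsi <- sum(p[[i]] * pt$dpsi)
    g[pt$idx_phi] <- g[pt$idx_phi] + wphi * as.numeric(pt$gphi)
    g[pt$idx_psi] <- g[pt$idx_psi] + wpsi * as.numeric(pt$gpsi)
  }
  # side chain-backbone terms (weights p_i)
  for (rec in sys$scbb_terms) {
    i <- rec$i; st <- sys$sites[[rec$site]]
    for (a in seq_len(rec$n_states)) {
      w <- p[[i]][a]
      if (w == 0) next
      g[res_span(i)] <- g[res_span(i)] +
        w * (as.numeric(rec$dy1[a, ] %*% sys$Jpos[[i]][[a]]) +
               as.numeric(rec$dn1[a, ] %*% sys$Jdir[[i]][[a]]))
      for (cc in st$jac)
        g[cc$idx] <- g[cc$idx] + w * as.numeric(rec$dy2[a, ] %*% cc$J)
      if (!is.null(st$jac_dir))
        for (cc in st$jac_dir)
          g[cc$idx] <- g[cc$idx] + w * as.numeric(rec$dn2[a, ] %*% cc$J)
      if (!is.null(st$dkappa))
        for (cc in st$dkappa)
          g[cc$idx] <- g[cc$idx] + w * rec$unit[a] * cc$g
    }
  }
  # side chain-side chain terms (weights p_ij)
  ne <- if (is.null(sys$edges)) 0L else nrow(sys$edges)
  for (e in seq_len(ne)) {
    i <- sys$edges[e, 1]; j <- sys$edges[e, 2]
    ni <- sys$beads[[i]]$n_states
    pij <- marginals$p_edges[[e]]
    terms <- sys$edge_terms[[e]]$terms
    for (b in seq_len(ncol(pij))) for (a in seq_len(nrow(pij))) {
      w <- pij[a, b]
      if (w == 0) next
      fe <- terms[[(b - 1L) * ni + a]]
      g[res_span(i)] <- g[res_span(i)] +
        w * (as.numeric(fe$dy1 %*% sys$Jpos[[i]][[a]]) +
               as.numeric(fe$dn1 %*% sys$Jdir[[i]][[a]]))
      g[res_span(j)] <- g[res_span(j)] +
        w * (as.numeric(fe$dy2 %*% sys$Jpos[[j]][[b]]) +
               as.numeric(fe$dn2 %*% sys$Jdir[[j]][[b]]))
    }
  }
  gm <- matrix(g, ncol = 3, byrow = TRUE)
  list(gradient = gm, forces = -gm, converged = marginals$converged)
}

#' Pull site forces back onto the defining backbone atoms
#'
#' Transfers a force acting on a derived site (O, H or bead) to the
#' backbone atoms it is constructed from, via the chain rule with the
#' site's placement Jacobian.  Linear in the applied force and exact for
#' rigid placements.
#'
#' @param site_forces list of entries `list(idx, J, force)`: flat
#'   coordinate indices, the 3 x length(idx) placement Jacobian, and the
#'   3-vector force on the site.
#' @param n_coords length of the flat backbone coordinate vector.
#' @return numeric vector of force increments on the backbone coordinates.
#' @export
pullback_forces <- function(site_forces, n_coords) {
  g <- numeric(n_coords)
  for (sf in site_forces)
    g[sf$idx] <- g[sf$idx] + as.numeric(sf$force %*% sf$J)
  g
}
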