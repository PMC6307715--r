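# Langevin dynamics of the backbone trace on the side-chain free-energy
# surface.  The potential is V_backbone + G^SC: harmonic bond and angle
# restraints at the ideal backbone geometry, a soft-sphere steric
# repulsion below 3 A, a tabulated Ramachandran statistical energy, a
# backbone hydrogen-bond energy proportional to the smooth confidence
# score, and the belief-propagated side-chain free energy.  Integration is
# a BAOAB splitting of Langevin dynamics (Verlet drift plus an exact
# Ornstein-Uhlenbeck thermostat), with Metropolis replica exchange across
# a temperature ladder.

default_backbone_springs <- function() {
  list(k_bond = 100, k_angle = 50, k_steric = 3, r_steric = 3,
       b_NCA = 1.453, b_CAC = 1.526, b_CN = 1.300,
       ang_NCAC = 109.5 * pi / 180, ang_CACN = 120 * pi / 180,
       ang_CNCA = 120 * pi / 180)
}

#' The printed replica-exchange temperature ladder
#' @return numeric vector of 14 temperatures.
#' @export
replica_temperature_ladder <- function() {
  c(0.500, 0.532, 0.566, 0.600, 0.636, 0.672, 0.709, 0.748, 0.787,
    0.828, 0.869, 0.912, 0.955, 1.000)
}

#' Simulation settings
#'
#' @param dt integration time step (default 0.009 time units).
#' @param thermalization Langevin thermalization time scale (friction is
#'   its inverse; default 0.135 time units).
#' @param temperatures replica temperature ladder (strictly increasing);
#'   a single value runs plain Langevin dynamics.
#' @param hbond_energy backbone hydrogen-bond strength in kT (negative).
#' @param seed RNG seed.
#' @param n_steps number of integration steps.
#' @param save_interval frames are stored every this many steps.
#' @param exchange_interval steps between replica-exchange attempts.
#' @param bp_tol,bp_max_iter,bp_lambda belief-propagation controls.
#' @param warm_start reuse the previous frame's beliefs to start BP.
#' @return list of settings.
#' @export
simulation_config <- function(dt = 0.009, thermalization = 0.135,
                              temperatures = 1.0, hbond_energy = -1.8,
                              seed = 1L, n_steps = 100L, save_interval = 10L,
                              exchange_interval = 10L, bp_tol = 1e-3,
                              bp_max_iter = 500L, bp_lambda = 0.4,
                              warm_start = TRUE) {
  stopifnot(dt > 0, all(diff(temperatures) > 0) || length(temperatures) == 1)
  list(dt = dt, thermalization = thermalization,
       temperatures = temperatures, hbond_energy = hbond_energy,
       seed = as.integer(seed), n_steps = as.integer(n_steps),
       save_interval = as.integer(save_interval),
       exchange_interval = as.integer(exchange_interval),
       bp_tol = bp_tol, bp_max_iter = as.integer(bp_max_iter),
       bp_lambda = bp_lambda, warm_start = warm_start,
       integrator = "BAOAB")
}

.angle_at <- function(A, B, C) {
  u <- A - B; v <- C - B
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
}

# gradient of the angle at B: 3 x 3 matrix (columns dA, dB, dC)
.angle_gradient <- function(A, B, C) {
  u <- A - B; v <- C - B
  nu <- vnorm(u); nv <- vnorm(v)
  ct <- max(-1, min(1, sum(u * v) / (nu * nv)))
  st <- sqrt(max(1e-12, 1 - ct^2))
  dA <- -(v / (nu * nv) - ct * u / nu^2) / st
  dC <- -(u / (nu * nv) - ct * v / nv^2) / st
  cbind(dA, -(dA + dC), dC)
}

#' Backbone potential energy and forces
#'
#' Harmonic bond springs at the ideal N-CA/CA-C/C-N lengths, harmonic
#' angle restraints at 109.5/120 degrees, soft-sphere repulsion below 3 A
#' between non-bonded backbone atoms, a Ramachandran statistical energy
#' (`-log` density, bilinear), and the backbone hydrogen-bond energy
#' `hbond_energy * sum(f)` over donor-acceptor pairs.
#'
#' @param chain a [backbone_chain()].
#' @param params a `parameter_set` (geometry, hydrogen-bond criteria,
#'   spring constants under `$backbone`).
#' @param rama a [rama_density()] used as the statistical potential.
#' @param hbond_energy hydrogen-bond strength (kT).
#' @param grad include analytic forces.
#' @return list with `energy`, a `breakdown` by term, and with `grad` the
#'   flat `gradient` and `forces` vectors (length 9 n).
#' @export
backbone_energy <- function(chain, params, rama = NULL,
                            hbond_energy = params$config$hbond_energy,
                            grad = FALSE) {
  bs <- params$backbone
  if (is.null(bs)) bs <- default_backbone_springs()
  n <- length(chain$residues)
  g <- numeric(9 * n)
  E_bond <- 0; E_ang <- 0; E_ster <- 0; E_rama <- 0; E_hb <- 0
  coords <- matrix(chain_coords(chain), ncol = 3, byrow = TRUE)
  add <- function(idx, v) g[idx] <<- g[idx] + v
  bond <- function(i1, w1, i2, w2, r0) {
    a <- coords[(i1 - 1) * 3 + match(w1, c("N", "CA", "C")), ]
    b <- coords[(i2 - 1) * 3 + match(w2, c("N", "CA", "C")), ]
    d <- a - b; r <- vnorm(d)
    E_bond <<- E_bond + 0.5 * bs$k_bond * (r - r0)^2
    if (grad) {
      f <- bs$k_bond * (r - r0) * d / r
      add(atom_cidx(i1, w1), f); add(atom_cidx(i2, w2), -f)
    }
  }
  angle <- function(iA, wA, iB, wB, iC, wC, th0) {
    A <- coords[(iA - 1) * 3 + match(wA, c("N", "CA", "C")), ]
    B <- coords[(iB - 1) * 3 + match(wB, c("N", "CA", "C")), ]
    C <- coords[(iC - 1) * 3 + match(wC, c("N", "CA", "C")), ]
    th <- .angle_at(A, B, C)
    E_ang <<- E_ang + 0.5 * bs$k_angle * (th - th0)^2
    if (grad) {
      G <- bs$k_angle * (th - th0) * .angle_gradient(A, B, C)
      add(atom_cidx(iA, wA), G[, 1]); add(atom_cidx(iB, wB), G[, 2])
      add(atom_cidx(iC, wC), G[, 3])
    }
  }
  for (i in seq_len(n)) {
    bond(i, "N", i, "CA", bs$b_NCA)
    bond(i, "CA", i, "C", bs$b_CAC)
    angle(i, "N", i, "CA", i, "C", bs$ang_NCAC)
    if (i < n) {
      bond(i, "C", i + 1, "N", bs$b_CN)
      angle(i, "CA", i, "C", i + 1, "N", bs$ang_CACN)
      angle(i, "C", i + 1, "N", i + 1, "CA", bs$ang_CNCA)
    }
  }
  # soft-sphere sterics between atoms more than 3 covalent bonds apart
  na <- 3 * n
  for (a in seq_len(na - 4)) {
    for (b in (a + 4):na) {
      d <- coords[a, ] - coords[b, ]
      r2 <- sum(d * d)
      if (r2 >= bs$r_steric^2) next
      r <- sqrt(r2)
      E_ster <- E_ster + bs$k_steric * (bs$r_steric - r)^2
      if (grad) {
        f <- -2 * bs$k_steric * (bs$r_steric - r) * d / r
        ia <- (a - 1) * 3 + 1:3; ib <- (b - 1) * 3 + 1:3
        add(ia, f); add(ib, -f)
      }
    }
  }
  if (!is.null(rama)) {
    Etab <- -log(pmax(rama$density, 1e-8))
    dih <- chain_dihedrals(chain)
    for (i in seq_len(n)) {
      if (is.na(dih$phi[i]) || is.na(dih$psi[i])) next
      bi <- .bilinear_periodic(Etab, rama$centers, dih$phi[i], dih$psi[i],
                               grad = grad)
      if (grad) {
        E_rama <- E_rama + bi$value
        gphi <- dihedral_gradient(chain$C[i - 1, ], chain$N[i, ],
                                  chain$CA[i, ], chain$C[i, ])
        idxp <- c(atom_cidx(i - 1, "C"), atom_cidx(i, "N"),
                  atom_cidx(i, "CA"), atom_cidx(i, "C"))
        add(idxp, bi$dx * as.numeric(gphi))
        gpsi <- dihedral_gradient(chain$N[i, ], chain$CA[i, ],
                                  chain$C[i, ], chain$N[i + 1, ])
        idxs <- c(atom_cidx(i, "N"), atom_cidx(i, "CA"),
                  atom_cidx(i, "C"), atom_cidx(i + 1, "N"))
        add(idxs, bi$dy * as.numeric(gpsi))
      } else E_rama <- E_rama + bi
    }
  }
  if (!is.null(hbond_energy) && hbond_energy != 0) {
    derived <- place_peptide_atoms(chain, params$geometry)
    dj <- if (grad) derived_atom_jacobians(chain, params$geometry) else NULL
    hb <- compute_hbonds(chain, derived, dj, params$hbond, grad = grad)
    for (p in hb$pairs) {
      E_hb <- E_hb + hbond_energy * p$f
      if (grad) for (cc in p$comps) add(cc$idx, hbond_energy * cc$g)
    }
  }
  E <- E_bond + E_ang + E_ster + E_rama + E_hb
  out <- list(energy = E,
              breakdown = c(bond = E_bond, angle = E_ang, steric = E_ster,
                            rama = E_rama, hbond = E_hb))
  if (grad) { out$gradient <- g; out$forces <- -g }
  out
}

#' One BAOAB Langevin-Verlet step
#'
#' Half kick, half drift, exact Ornstein-Uhlenbeck velocity refresh at the
#' configured temperature (friction = 1/thermalization), half drift, force
#' refresh, half kick.  With zero friction this reduces to velocity
#' Verlet (NVE); masses are unit.
#'
#' @param state list with positions `x`, velocities `v`, and forces `f`
#'   (flat numeric vectors).
#' @param forces function(x) returning the force vector at x.
#' @param config a [simulation_config()]; `temperature` is taken from
#'   `state$temperature` if present, else the first ladder entry.
#' @return updated state (forces at the new positions included).
#' @export
langevin_step <- function(state, forces, config) {
  dt <- config$dt
  Temp <- if (!is.null(state$temperature)) state$temperature
  else config$temperatures[1]
  gam <- if (config$thermalization > 0) 1 / config$thermalization else 0
  x <- state$x; v <- state$v
  f <- if (is.null(state$f)) forces(x) else state$f
  v <- v + 0.5 * dt * f
  x <- x + 0.5 * dt * v
  if (gam > 0) {
    c1 <- exp(-gam * dt)
    c2 <- sqrt((1 - c1^2) * Temp)
    v <- c1 * v + c2 * stats::rnorm(length(v))
  }
  x <- x + 0.5 * dt * v
  f <- forces(x)
  v <- v + 0.5 * dt * f
  state$x <- x; state$v <- v; state$f <- f
  state
}

#' Metropolis replica-exchange sweep
#'
#' Attempts swaps between adjacent temperatures (even pairs on phase 0,
#' odd pairs on phase 1) with acceptance `min(1, exp(dbeta * dE))`; on
#' acceptance the replicas exchange temperatures and velocities are
#' rescaled by `sqrt(T_new/T_old)`.
#'
#' @param replicas list of states, each with `x`, `v`, `temperature`, and
#'   potential `energy`.
#' @param phase 0 or 1: which alternating set of adjacent pairs to try.
#' @return list with updated `replicas` and logical `accepted` per
#'   attempted pair.
#' @export
replica_exchange_step <- function(replicas, phase = 0L) {
  ord <- order(vapply(replicas, `[[`, numeric(1), "temperature"))
  nr <- length(replicas)
  accepted <- logical(0)
  starts <- seq(1 + (phase %% 2), nr - 1, by = 2)
  for (s in starts) {
    a <- ord[s]; b <- ord[s + 1]
    Ta <- replicas[[a]]$temperature; Tb <- replicas[[b]]$temperature
    Ea <- replicas[[a]]$energy; Eb <- replicas[[b]]$energy
    dlt <- (1 / Ta - 1 / Tb) * (Ea - Eb)
    acc <- dlt >= 0 || stats::runif(1) < exp(dlt)
    accepted <- c(accepted, acc)
    if (acc) {
      replicas[[a]]$temperature <- Tb
      replicas[[b]]$temperature <- Ta
      replicas[[a]]$v <- replicas[[a]]$v * sqrt(Tb / Ta)
      replicas[[b]]$v <- replicas[[b]]$v * sqrt(Ta / Tb)
    }
  }
  list(replicas = replicas, accepted = accepted)
}

#' Run backbone Langevin dynamics on the side-chain free-energy surface
#'
#' The six-step inner loop per integration step: place O/H, place beads,
#' solve belief propagation, differentiate the free energy, pull forces
#' back onto N/CA/C, and advance with Langevin dynamics.  With more than
#' one ladder temperature, replicas run in lock step with Metropolis
#' exchanges every `exchange_interval` steps.
#'
#' @param chain starting [backbone_chain()].
#' @param params a `parameter_set`.
#' @param rama a [rama_density()] for the Ramachandran term (optional).
#' @param config a [simulation_config()].
#' @param include_side_chain include G^SC in the potential (disable for
#'   backbone-only tests).
#' @return object of class `trajectory`: per replica a list of saved
#'   coordinate frames, an `energies` data frame (step, replica,
#'   temperature, V_backbone, G_sc, total, kinetic), and the config.
#' @export
run_simulation <- function(chain, params, rama = NULL,
                           config = simulation_config(),
                           include_side_chain = TRUE) {
  n <- length(chain$residues)
  x0 <- chain_coords(chain)
  temps <- config$temperatures
  nr <- length(temps)
  .with_seed(config$seed, {
    bp_store <- vector("list", nr)
    eval_pot <- function(x, r) {
      ch <- chain_from_coords(chain, x)
      be <- backbone_energy(ch, params, rama, grad = TRUE)
      Gsc <- 0
      gr <- be$gradient
      if (include_side_chain) {
        sys <- sc_system(ch, params, grad = TRUE)
        init <- if (isTRUE(config$warm_start)) bp_store[[r]] else NULL
        # warm starts are only valid while the graph is unchanged
        if (!is.null(init) && !identical(attr(init, "edges"), sys$edges))
          init <- NULL
        ms <- solve_marginals(sys$v, sys$edges, sys$v_ij,
                              lambda = config$bp_lambda, tol = config$bp_tol,
                              max_iter = config$bp_max_iter, init = init)
        bp_store[[r]] <<- if (isTRUE(config$warm_start) &&
                              isTRUE(ms$converged)) ms$state else NULL
        if (!is.null(bp_store[[r]]))
          attr(bp_store[[r]], "edges") <- sys$edges
        fr <- side_chain_forces(ch, ms, params, system = sys)
        Gsc <- ms$G
        gr <- gr + as.numeric(t(fr$gradient))
      }
      list(f = -gr, V = be$energy, G = Gsc)
    }
    replicas <- vector("list", nr)
    for (r in seq_len(nr)) {
      pot <- eval_pot(x0, r)
      replicas[[r]] <- list(x = x0, v = numeric(length(x0)), f = pot$f,
                            temperature = temps[r], energy = pot$V + pot$G,
                            V = pot$V, G = pot$G)
    }
    frames <- lapply(seq_len(nr), function(r) list(x0))
    en <- NULL
    log_row <- function(step) {
      for (r in seq_len(nr)) {
        kin <- 0.5 * sum(replicas[[r]]$v^2)
        en <<- rbind(en, data.frame(step = step, replica = r,
                                    temperature = replicas[[r]]$temperature,
                                    V_backbone = replicas[[r]]$V,
                                    G_sc = replicas[[r]]$G,
                                    total = replicas[[r]]$energy,
                                    kinetic = kin))
      }
    }
    log_row(0L)
    if (config$n_steps > 0) {
      for (step in seq_len(config$n_steps)) {
        for (r in seq_len(nr)) {
          st <- replicas[[r]]
          pot_env <- new.env(parent = emptyenv())
          ffun <- function(x) {
            p <- eval_pot(x, r)
            assign("last", p, envir = pot_env)
            p$f
          }
          st <- langevin_step(st, ffun, config)
          p <- get("last", envir = pot_env)
          st$energy <- p$V + p$G; st$V <- p$V; st$G <- p$G
          replicas[[r]] <- st
        }
        if (nr > 1 && step %% config$exchange_interval == 0) {
          rx <- replica_exchange_step(replicas,
                                      phase = (step %/% config$exchange_interval) %% 2)
          replicas <- rx$replicas
        }
        if (step %% config$save_interval == 0) {
          for (r in seq_len(nr))
            frames[[r]][[length(frames[[r]]) + 1L]] <- replicas[[r]]$x
          log_row(step)
        }
      }
    }
    structure(list(frames = frames, energies = en, config = config,
                   chain = chain),
              class = "trajectory")
  })
}
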