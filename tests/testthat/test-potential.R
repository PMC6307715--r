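random_bead_pair <- function(r = NULL) {
  y1 <- rnorm(3)
  u <- unit3(rnorm(3))
  if (is.null(r)) r <- runif(1, 1, 6.5)
  y2 <- y1 + r * u
  list(y1 = y1, n1 = unit3(rnorm(3)), y2 = y2, n2 = unit3(rnorm(3)))
}

perturbed_pp <- function(seed = 5, cutoff = 7) {
  set.seed(seed)
  pp <- default_pair_params(cutoff, directional = TRUE)
  K <- length(pp$radial)
  pp$radial <- pp$radial + rnorm(K, sd = 0.5); pp$radial[K] <- 0
  pp$angular <- rnorm(K, sd = 0.5); pp$angular[K] <- 0
  pp$ang1 <- rnorm(ANGULAR_KNOTS, sd = 0.3)
  pp$ang2 <- rnorm(ANGULAR_KNOTS, sd = 0.3)
  pp
}

test_that("pair energy vanishes beyond the cutoff and for kappa = 0", {
  pp <- perturbed_pp()
  g <- random_bead_pair(r = 7.1)
  expect_identical(pair_energy(g$y1, g$n1, g$y2, g$n2, pp), 0)
  g2 <- random_bead_pair(r = 3)
  expect_identical(pair_energy(g2$y1, g2$n1, g2$y2, g2$n2, pp, kappa = 0), 0)
  expect_error(pair_energy(g$y1, g$n1, g$y1, g$n2, pp), "r = 0")
})

test_that("pair energy equals an oracle-spline composition of the formula", {
  set.seed(6)
  pp <- perturbed_pp(6)
  for (t in 1:20) {
    g <- random_bead_pair()
    r <- vnorm(g$y1 - g$y2)
    u <- (g$y1 - g$y2) / r
    x1 <- -sum(g$n1 * u); x2 <- sum(g$n2 * u)
    ha <- 2 / (ANGULAR_KNOTS - 1)
    want <- oracle_clamped_spline(pp$radial, 0, 0.5, r) +
      oracle_clamped_spline(exp(pp$ang1), -1, ha, x1) *
      oracle_clamped_spline(exp(pp$ang2), -1, ha, x2) *
      oracle_clamped_spline(pp$angular, 0, 0.5, r)
    got <- pair_energy(g$y1, g$n1, g$y2, g$n2, pp)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("pair energy is continuous through the cutoff", {
  pp <- perturbed_pp(7)
  y1 <- c(0, 0, 0); n1 <- c(0, 0, 1); n2 <- unit3(c(1, 1, 0.5))
  rs <- seq(0.5, 7.5, by = 0.002)
  vals <- vapply(rs, function(r)
    pair_energy(y1, n1, c(r, 0, 0), n2, pp), numeric(1))
  expect_lt(max(abs(diff(vals))), 0.05)    # Lipschitz x grid step
  expect_lt(abs(vals[sum(rs < 7)]), 0.01)  # approaches 0 at the cutoff
  expect_true(all(vals[rs >= 7] == 0))
})

test_that("pair-energy gradients match finite differences", {
  set.seed(8)
  pp <- perturbed_pp(8)
  g <- random_bead_pair(r = 4.3)
  fe <- pair_energy_full(g$y1, g$n1, g$y2, g$n2, pp, kappa = 0.7, grad = TRUE)
  h <- 1e-6
  for (nm in c("y1", "y2", "n1", "n2")) {
    for (d in 1:3) {
      gp <- g; gm <- g
      gp[[nm]][d] <- gp[[nm]][d] + h; gm[[nm]][d] <- gm[[nm]][d] - h
      fd <- (pair_energy(gp$y1, gp$n1, gp$y2, gp$n2, pp, 0.7) -
               pair_energy(gm$y1, gm$n1, gm$y2, gm$n2, pp, 0.7)) / (2 * h)
      expect_lt(abs(fd - fe[[paste0("d", nm)]][d]), 1e-6)
    }
  }
})

test_that("hydrogen-bond confidence honors the printed endpoints", {
  # collinear N-H...O=C geometry along x
  N <- c(0, 0, 0); H <- c(1.01, 0, 0)
  mk <- function(rHO) list(O = H + c(rHO, 0, 0), C = H + c(rHO + 1.23, 0, 0))
  g <- mk(3.0)
  expect_identical(hbond_confidence(H, g$O, N, g$C), 0)
  g <- mk(1.9)
  f0 <- hbond_confidence(H, g$O, N, g$C)
  expect_gt(f0, 0.9)                    # mid-plateau, fully aligned
  # 47 degrees off co-linear on the acceptor side halves the score
  a <- 47 * pi / 180
  g <- mk(1.9)
  C2 <- g$O + 1.23 * c(cos(a), sin(a), 0)
  f47 <- hbond_confidence(H, g$O, N, C2)
  expect_equal(f47 / f0, 0.5, tolerance = 1e-6)
  # missing atoms give zero
  expect_identical(hbond_confidence(NULL, g$O, N, g$C), 0)
})

test_that("hydrogen-bond score decreases monotonically off co-linear", {
  N <- c(0, 0, 0); H <- c(1.01, 0, 0); O <- H + c(1.9, 0, 0)
  angles <- seq(0, 80, by = 5) * pi / 180
  fs <- vapply(angles, function(a)
    hbond_confidence(H, O, N, O + 1.23 * c(cos(a), sin(a), 0)),
    numeric(1))
  expect_true(all(diff(fs) <= 1e-12))
})

test_that("hydrogen-bond gradients match finite differences", {
  set.seed(9)
  N <- c(0, 0.2, -0.1); H <- c(1.0, 0.1, 0.05)
  O <- c(2.8, 0.4, -0.2); C <- c(3.9, -0.3, 0.4)
  res <- hbond_confidence(H, O, N, C, grad = TRUE)
  h <- 1e-7
  pts <- list(H = H, O = O, N = N, C = C)
  for (nm in names(pts)) {
    for (d in 1:3) {
      pp_ <- pts; pm <- pts
      pp_[[nm]][d] <- pp_[[nm]][d] + h; pm[[nm]][d] <- pm[[nm]][d] - h
      fd <- (hbond_confidence(pp_$H, pp_$O, pp_$N, pp_$C) -
               hbond_confidence(pm$H, pm$O, pm$N, pm$C)) / (2 * h)
      expect_lt(abs(fd - res[[paste0("d", nm)]][d]), 1e-6)
    }
  }
})

test_that("local energies match a direct per-state recomputation", {
  params <- fixture_params_perturbed()
  ch <- fixture_chain(2, seed = 61, noise_deg = 5)
  # move the two residues close enough to interact
  en <- build_local_energies(ch, params)
  sys <- en$system
  if (nrow(sys$edges) == 1) {
    i <- sys$edges[1, 1]; j <- sys$edges[1, 2]
    key <- sc_pair_key(ch$residues[i], ch$residues[j])
    pp <- params$pair[[key]]
    first_i <- ch$residues[i] <= ch$residues[j]
    for (a in seq_len(sys$beads[[i]]$n_states))
      for (b in seq_len(sys$beads[[j]]$n_states)) {
        want <- if (first_i)
          pair_energy(sys$beads[[i]]$pos[a, ], sys$beads[[i]]$dir[a, ],
                      sys$beads[[j]]$pos[b, ], sys$beads[[j]]$dir[b, ], pp)
        else
          pair_energy(sys$beads[[j]]$pos[b, ], sys$beads[[j]]$dir[b, ],
                      sys$beads[[i]]$pos[a, ], sys$beads[[i]]$dir[a, ], pp)
        expect_lt(abs(sys$v_ij[[1]][a, b] - want), 1e-12)
      }
  }
  # v_i dimensions match the state counts
  for (i in seq_along(ch$residues))
    expect_length(en$v[[i]], params$types[[ch$residues[i]]]$n_states)
})

test_that("single-state residues give length-1 energy vectors", {
  params <- fixture_params()
  ch <- gen_toy_protein(13, 3, "helix", types = "ALA")
  en <- build_local_energies(ch, params)
  expect_true(all(lengths(en$v) == 1L))
})
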