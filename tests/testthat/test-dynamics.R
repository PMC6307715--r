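test_that("ideal-geometry chains have zero spring and angle energy", {
  params <- fixture_params()
  ch <- gen_toy_protein(5, 8, "helix", noise_deg = 0)
  be <- backbone_energy(ch, params, rama = NULL, hbond_energy = 0)
  expect_lt(be$breakdown[["bond"]], 1e-20)
  expect_lt(be$breakdown[["angle"]], 1e-20)
})

test_that("sterics vanish when all non-bonded atoms exceed 3 A", {
  params <- fixture_params()
  ch <- gen_toy_protein(6, 6, "extended", noise_deg = 0)
  be <- backbone_energy(ch, params, rama = NULL, hbond_energy = 0)
  expect_identical(be$breakdown[["steric"]], 0)
})

test_that("every backbone term's force matches finite differences", {
  params <- fixture_params()
  rama <- fixture_rama()
  ch <- fixture_chain(7, seed = 31, noise_deg = 12)
  be <- backbone_energy(ch, params, rama, grad = TRUE)
  x0 <- chain_coords(ch)
  f <- function(x) backbone_energy(chain_from_coords(ch, x), params, rama)$energy
  h <- 1e-6
  set.seed(32)
  for (k in sample(length(x0), 12)) {
    xp <- x0; xm <- x0
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    fd <- (f(xp) - f(xm)) / (2 * h)
    expect_lt(abs(fd - be$gradient[k]) / max(abs(fd), 1e-4), 1e-5)
  }
})

test_that("force-free frictionless motion is a straight line", {
  cfg <- simulation_config(dt = 0.009, thermalization = 0, temperatures = 1)
  st <- list(x = c(1, 2), v = c(0.5, -0.2), f = c(0, 0))
  st2 <- langevin_step(st, function(x) c(0, 0), cfg)
  expect_equal(st2$x, st$x + st$v * cfg$dt, tolerance = 1e-14)
  expect_equal(st2$v, st$v, tolerance = 1e-14)
})

test_that("frictionless Verlet conserves energy to high accuracy", {
  cfg <- simulation_config(dt = 0.009, thermalization = 0, temperatures = 1)
  k <- 2.5
  ffun <- function(x) -k * x
  st <- list(x = 1, v = 0.3, f = ffun(1))
  E0 <- 0.5 * st$v^2 + 0.5 * k * st$x^2
  worst <- 0
  for (s in 1:10000) {
    st <- langevin_step(st, ffun, cfg)
    E <- 0.5 * st$v^2 + 0.5 * k * st$x^2
    worst <- max(worst, abs(E - E0) / E0)
  }
  expect_lt(worst, 1e-3)
})

test_that("Langevin sampling of a harmonic well reproduces equipartition", {
  k <- 2.5; Temp <- 0.7
  cfg <- simulation_config(dt = 0.05, thermalization = 0.5,
                           temperatures = Temp)
  ffun <- function(x) -k * x
  set.seed(33)
  st <- list(x = 0, v = 0, f = 0, temperature = Temp)
  nsteps <- 60000L; burn <- 5000L
  xs <- numeric(nsteps)
  for (s in seq_len(nsteps)) {
    st <- langevin_step(st, ffun, cfg)
    xs[s] <- st$x
  }
  xs <- xs[(burn + 1):nsteps]
  # batch-means standard error to respect autocorrelation
  nb <- 50L
  bm <- colMeans(matrix(xs^2, ncol = nb))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(xs^2) - Temp / k), 3 * se)
})

test_that("equal-temperature replicas always exchange", {
  reps <- list(list(x = 1, v = 1, temperature = 0.7, energy = 5),
               list(x = 2, v = 1, temperature = 0.7, energy = -3))
  # identical temperatures: dbeta = 0, acceptance 1 regardless of energies
  set.seed(34)
  out <- replica_exchange_step(reps, phase = 0)
  expect_true(all(out$accepted))
})

test_that("the configured ladder matches the fourteen printed temperatures", {
  expect_identical(replica_temperature_ladder(),
                   c(0.500, 0.532, 0.566, 0.600, 0.636, 0.672, 0.709, 0.748,
                     0.787, 0.828, 0.869, 0.912, 0.955, 1.000))
  cfg <- simulation_config(temperatures = replica_temperature_ladder())
  expect_length(cfg$temperatures, 14L)
  expect_true(all(diff(cfg$temperatures) > 0))
})

test_that("replica exchange preserves per-temperature distributions", {
  # two-temperature harmonic system: energies per temperature after
  # exchange must match single-temperature references (KS test)
  k <- 1.8; temps <- c(0.6, 1.2)
  cfg <- simulation_config(dt = 0.05, thermalization = 0.4,
                           temperatures = temps)
  ffun <- function(x) -k * x
  run_single <- function(Temp, n, seed) {
    set.seed(seed)
    st <- list(x = 0, v = 0, f = 0, temperature = Temp)
    out <- numeric(n)
    for (s in seq_len(n)) { st <- langevin_step(st, ffun, cfg); out[s] <- st$x }
    out
  }
  set.seed(35)
  reps <- lapply(temps, function(Tt)
    list(x = 0, v = 0, f = 0, temperature = Tt, energy = 0))
  n <- 30000L
  xs <- list(numeric(0), numeric(0))
  for (s in seq_len(n)) {
    for (r in 1:2) {
      st <- reps[[r]]
      st <- langevin_step(st, ffun, cfg)
      st$energy <- 0.5 * k * st$x^2
      reps[[r]] <- st
    }
    if (s %% 10 == 0) reps <- replica_exchange_step(reps)$replicas
    if (s > 2000 && s %% 7 == 0) {
      for (r in 1:2) {
        slot <- which(temps == reps[[r]]$temperature)
        xs[[slot]] <- c(xs[[slot]], reps[[r]]$x)
      }
    }
  }
  for (slot in 1:2) {
    ref <- run_single(temps[slot], 30000L, seed = 100 + slot)
    ref <- ref[seq(2001, 30000, by = 7)]
    ks <- suppressWarnings(stats::ks.test(xs[[slot]][seq(1, length(xs[[slot]]), by = 8)],
                                          ref[seq(1, length(ref), by = 8)]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("zero steps return only the initial frame; seeds reproduce runs", {
  params <- fixture_params()
  rama <- fixture_rama()
  ch <- fixture_chain(6, seed = 36)
  t0 <- run_simulation(ch, params, rama,
                       simulation_config(n_steps = 0, seed = 2,
                                         temperatures = 0.8))
  expect_length(t0$frames[[1]], 1L)
  expect_identical(t0$frames[[1]][[1]], chain_coords(ch))
  cfg <- simulation_config(n_steps = 10, save_interval = 5, seed = 2,
                           temperatures = 0.8)
  t1 <- run_simulation(ch, params, rama, cfg)
  t2 <- run_simulation(ch, params, rama, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  expect_length(t1$frames[[1]], 10 %/% 5 + 1)
})

test_that("warm-started BP agrees with cold starts along a trajectory", {
  params <- fixture_params()
  rama <- fixture_rama()
  ch <- fixture_chain(6, seed = 37)
  cfg <- simulation_config(n_steps = 6, save_interval = 1, seed = 4,
                           temperatures = 0.9, bp_tol = 1e-6,
                           bp_max_iter = 2000)
  traj <- run_simulation(ch, params, rama, cfg)
  for (k in seq_along(traj$frames[[1]])) {
    x <- traj$frames[[1]][[k]]
    c2 <- chain_from_coords(ch, x)
    ms_cold <- side_chain_marginals(c2, params, tol = 1e-6, max_iter = 2000)
    # the trajectory's logged G used warm starts; both must agree
    expect_equal(traj$energies$G_sc[traj$energies$step == (k - 1) * 1][1],
                 ms_cold$G, tolerance = 1e-3)
  }
})

test_that("lower-temperature dynamics settle at lower mean energy", {
  k <- 2.0
  cfg_lo <- simulation_config(dt = 0.05, thermalization = 0.4, temperatures = 0.5)
  cfg_hi <- simulation_config(dt = 0.05, thermalization = 0.4, temperatures = 1.0)
  ffun <- function(x) -k * x
  mean_E <- function(cfg, Temp, seed) {
    set.seed(seed)
    st <- list(x = 0, v = 0, f = 0, temperature = Temp)
    es <- numeric(20000)
    for (s in 1:20000) {
      st <- langevin_step(st, ffun, cfg)
      es[s] <- 0.5 * st$v^2 + 0.5 * k * st$x^2
    }
    mean(es[5001:20000])
  }
  expect_lt(mean_E(cfg_lo, 0.5, 41), mean_E(cfg_hi, 1.0, 42))
})
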