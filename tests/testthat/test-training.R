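small_example <- function(n = 5, seed = 55) {
  params <- fixture_params()
  ch <- fixture_chain(n, seed = seed)
  gen_training_set(params, list(ch), seed = seed + 1)[[1]]
}

test_that("a lone residue with a uniform prior has gap log n", {
  params <- fixture_params()
  ch <- gen_toy_protein(23, 1, "helix", types = "VAL")
  nst <- params$types$VAL$n_states
  # flatten the prior so every state is equally likely and no neighbors exist
  params$types$VAL$rot_prior[] <- 0
  params$types$VAL$prior_indep[] <- 0
  params$config$sc_bb <- FALSE
  ex <- training_example(ch, 2L, params)
  expect_equal(energy_gap(ex, params), log(nst), tolerance = 1e-9)
})

test_that("with exact enumeration the gap is a negative log probability", {
  ex <- small_example(5)
  params <- fixture_params()
  gap <- energy_gap(ex, params, solver = "exact")
  p <- exp(-gap)
  expect_gt(p, 0)
  expect_lte(p, 1)
  # BP agrees closely on this small system
  gap_bp <- energy_gap(ex, params, tol = 1e-9, max_iter = 5000)
  expect_lt(abs(gap - gap_bp), 0.05)
})

test_that("the gap is invariant to constant shifts of one residue's energies", {
  ex <- small_example(4, seed = 56)
  params <- fixture_params()
  g1 <- energy_gap(ex, params, solver = "exact")
  tp <- ex$chain$residues[2]
  params$types[[tp]]$rot_prior <- params$types[[tp]]$rot_prior + 2.5
  params$types[[tp]]$prior_indep <- params$types[[tp]]$prior_indep + 2.5
  g2 <- energy_gap(ex, params, solver = "exact")
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("invalid native states are rejected", {
  params <- fixture_params()
  ch <- fixture_chain(3, seed = 57)
  expect_error(training_example(ch, rep(99L, 3), params), "out of range")
})

test_that("the parametric gradient matches finite differences", {
  params <- fixture_params_perturbed()
  ex <- small_example(5, seed = 58)
  th <- flatten_params(params)
  lay <- attr(th, "layout")
  g <- parameter_gradient(ex, params, tol = 1e-10, max_iter = 20000)
  h <- 1e-5
  set.seed(59)
  for (k in sample(length(th), 8)) {
    tp <- th; tm <- th
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    fd <- (energy_gap(ex, unflatten_params(params, tp, lay),
                      tol = 1e-10, max_iter = 20000) -
             energy_gap(ex, unflatten_params(params, tm, lay),
                        tol = 1e-10, max_iter = 20000)) / (2 * h)
    expect_lt(abs(fd - g[k]) / max(abs(fd), 1e-5), 1e-3)
  }
})

test_that("absent residue-type pairs get exactly zero gradient", {
  params <- fixture_params()
  ch <- gen_toy_protein(24, 5, "random", types = c("SER", "VAL"))
  ex <- gen_training_set(params, list(ch), seed = 25)[[1]]
  g <- parameter_gradient(ex, params)
  lay <- param_layout(params)
  # LEU never occurs, so every LEU-involving block is untouched
  for (k in names(lay)) {
    if (!grepl("LEU", k)) next
    ent <- lay[[k]]
    expect_true(all(g[unlist(ent[-1])] == 0))
  }
})

test_that("regularization vanishes exactly on its null configuration", {
  params <- fixture_params()
  for (k in names(params$pair)) {
    pp <- params$pair[[k]]
    K <- length(pp$radial)
    # linear-in-index radial through (5, ..., 0): zero second difference,
    # contact knot at 5
    pp$radial <- seq(5, 0, length.out = K)
    pp$angular <- numeric(K)
    pp$ang1 <- numeric(ANGULAR_KNOTS)
    pp$ang2 <- numeric(ANGULAR_KNOTS)
    params$pair[[k]] <- pp
  }
  r <- regularization(params)
  expect_equal(as.numeric(r), 0, tolerance = 1e-20)
  # and is strictly positive once any condition is violated
  params$pair[[1]]$radial[1] <- 4
  expect_gt(as.numeric(regularization(params)), 0)
})

test_that("regularization gradient matches finite differences", {
  params <- fixture_params_perturbed()
  th <- flatten_params(params)
  lay <- attr(th, "layout")
  w <- c(smooth = 0.7, dir = 0.3, core = 1.1)
  r <- regularization(params, w)
  g <- attr(r, "grad")
  h <- 1e-6
  set.seed(60)
  for (k in sample(length(th), 8)) {
    tp <- th; tm <- th
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    fd <- (as.numeric(regularization(unflatten_params(params, tp, lay), w)) -
             as.numeric(regularization(unflatten_params(params, tm, lay), w))) /
      (2 * h)
    expect_lt(abs(fd - g[k]), 1e-5)
  }
})

test_that("zero learning rate leaves parameters untouched", {
  params <- fixture_params()
  ds <- lapply(1:3, function(s) small_example(4, seed = 60 + s))
  cfg <- optimizer_config(alpha = 0, steps = 5, minibatch = 2, seed = 3)
  fit <- train(ds, params, cfg)
  expect_identical(flatten_params(fit$params), flatten_params(params))
})

test_that("identical seeds give bit-identical loss traces", {
  params <- fixture_params()
  ds <- lapply(1:4, function(s) small_example(4, seed = 70 + s))
  cfg <- optimizer_config(steps = 5, minibatch = 2, seed = 11)
  f1 <- train(ds, params, cfg)
  f2 <- train(ds, params, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$theta, f2$theta)
})

test_that("training reduces the loss on a small planted problem", {
  base <- ablation_preset(fixture_params(), "isotropic_only")
  plant <- base
  set.seed(91)
  for (k in names(plant$pair)) {
    pp <- plant$pair[[k]]
    K <- length(pp$radial)
    r <- seq(0, pp$cutoff, length.out = K)
    pp$radial <- pp$radial - 1.2 * exp(-0.5 * ((r - 4.5) / 0.9)^2)
    pp$radial[K] <- 0
    plant$pair[[k]] <- pp
  }
  chains <- lapply(1:30, function(s)
    gen_toy_protein(300 + s, 6, "random",
                    types = c("ALA", "SER", "VAL", "LEU"), noise_deg = 10))
  ds <- gen_training_set(plant, chains, seed = 92)
  cfg <- optimizer_config(steps = 40, minibatch = 30, seed = 13, tol = 1e-4)
  fit <- train(ds, base, cfg)
  expect_lt(tail(fit$trace$egap, 1), fit$trace$egap[1] - 0.5)
})

test_that("the loss at the planted truth undercuts perturbed parameters", {
  base <- ablation_preset(fixture_params(), "isotropic_only")
  chains <- lapply(1:20, function(s)
    gen_toy_protein(400 + s, 6, "random",
                    types = c("ALA", "SER", "VAL", "LEU"), noise_deg = 10))
  ds <- gen_training_set(base, chains, seed = 94)
  e_truth <- mean_energy_gap(ds, base, tol = 1e-5)
  th <- flatten_params(base)
  lay <- attr(th, "layout")
  set.seed(95)
  wins <- 0L
  for (t in 1:10) {
    pert <- unflatten_params(base, th + rnorm(length(th), sd = 0.5), lay)
    if (mean_energy_gap(ds, pert, tol = 1e-5) >= e_truth) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("chi1 accuracy handles forced-correct and excluded cases", {
  params <- fixture_params()
  ch <- gen_toy_protein(26, 4, "helix", types = "ALA")
  ds <- list(training_example(ch, rep(1L, 4), params))
  acc <- chi1_accuracy(ds, params)
  expect_true(is.nan(acc))
  expect_identical(attr(acc, "n"), 0L)
  # forcing predictions equal to natives gives accuracy 1: use the
  # no-interaction prior and set the native to its argmax
  ch2 <- fixture_chain(5, seed = 27)
  p0 <- ablation_preset(params, "no_interactions")
  ms <- side_chain_marginals(ch2, p0)
  nat <- vapply(ms$p, which.max, integer(1))
  ds2 <- list(training_example(ch2, nat, params))
  expect_equal(as.numeric(chi1_accuracy(ds2, params, prior_only = TRUE)), 1)
})

test_that("ablation switches change the model in the expected direction", {
  params <- fixture_params_perturbed()
  ex <- small_example(6, seed = 63)
  full <- energy_gap(ex, params, tol = 1e-6, max_iter = 3000)
  noint <- energy_gap(ex, ablation_preset(params, "no_interactions"),
                      tol = 1e-6, max_iter = 3000)
  expect_false(isTRUE(all.equal(full, noint)))
  iso <- ablation_preset(params, "isotropic_only")
  expect_true(all(!vapply(iso$pair, `[[`, TRUE, "directional")))
  rep_ <- ablation_preset(params, "repulsive_only")
  expect_true(all(vapply(rep_$pair, function(p) all(p$radial >= 0), TRUE)))
  c10 <- ablation_preset(params, "cutoff10")
  expect_identical(c10$pair[[1]]$cutoff, 10)
  expect_identical(ablation_preset(params, "sc_sc_only")$config$sc_bb, FALSE)
  expect_identical(ablation_preset(params, "sc_bb_only")$config$sc_sc, FALSE)
})

test_that("RANSAC retains power-law chains and removes planted outliers", {
  set.seed(64)
  mk <- function(n, rg) {
    ch <- gen_toy_protein(sample.int(1e6, 1), n, "random", noise_deg = 10)
    # rescale coordinates so Rg is exactly as requested
    f <- rg / radius_of_gyration(ch)
    ch$N <- ch$N * f; ch$CA <- ch$CA * f; ch$C <- ch$C * f
    ch
  }
  ns <- sample(20:200, 40, replace = TRUE)
  chains <- lapply(ns, function(n) mk(n, 2.2 * n^0.38))
  keep <- filter_nonglobular(chains, seed = 2)
  expect_true(all(keep$inliers))
  # one 5x outlier is removed
  chains2 <- c(chains, list(mk(80, 5 * 2.2 * 80^0.38)))
  keep2 <- filter_nonglobular(chains2, seed = 2)
  expect_false(keep2$inliers[41])
  expect_true(mean(keep2$inliers[1:40]) > 0.95)
  # planted 10% outliers are recovered
  lab <- c(rep(TRUE, 36), rep(FALSE, 4))
  chains3 <- c(chains[1:36], lapply(1:4, function(k)
    mk(sample(20:200, 1), runif(1, 4, 6) * 2.2 * 80^0.38)))
  keep3 <- filter_nonglobular(chains3, seed = 3)
  expect_gte(mean(keep3$inliers == lab), 0.95)
  expect_warning(filter_nonglobular(chains[1:3]), "skipped")
})
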