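test_that("zero energies initialize to uniform positive beliefs", {
  v <- list(c(0, 0, 0), c(0, 0))
  st <- bp_initialize(v, matrix(c(1L, 2L), 1), list(matrix(0, 3, 2)))
  expect_equal(st$b[[1]], rep(1 / 3, 3))
  expect_equal(st$b[[2]], rep(1 / 2, 2))
  expect_true(all(unlist(st$m_ji) > 0))
})

test_that("round-0 messages equal the hand-summed interaction average", {
  v <- list(c(0.3, -0.2), c(0.1, 0.5))
  W <- matrix(c(0.4, -0.1, 0.2, 0.3), 2, 2)
  st <- bp_initialize(v, matrix(c(1L, 2L), 1), list(W))
  b2 <- exp(-v[[2]]) / sum(exp(-v[[2]]))
  want <- as.numeric(exp(-W) %*% b2)
  expect_equal(st$m_ji[[1]], want / sum(want), tolerance = 1e-12)
})

test_that("one damped iteration matches a hand evaluation of the update", {
  v <- list(c(0.3, -0.2), c(0.1, 0.5))
  W <- matrix(c(0.4, -0.1, 0.2, 0.3), 2, 2)
  edges <- matrix(c(1L, 2L), 1)
  lam <- 0.4
  st0 <- bp_initialize(v, edges, list(W))
  st1 <- bp_iterate(st0, v, edges, list(W), lambda = lam)
  # hand: cavity of node 2 with respect to the (1,2) message
  cav2 <- st0$b[[2]] / st0$m_ij[[1]]
  m_new <- as.numeric(exp(-W) %*% cav2)
  m_new <- m_new / sum(m_new)
  raw <- exp(-v[[1]]) * m_new
  raw <- raw / sum(raw)
  want <- lam * st0$b[[1]] + (1 - lam) * raw
  expect_equal(st1$b[[1]], want / sum(want), tolerance = 1e-12)
})

test_that("full damping freezes the node beliefs", {
  set.seed(81)
  sys <- random_tree_system(5)
  st0 <- bp_initialize(sys$v, sys$edges, sys$v_ij)
  st1 <- bp_iterate(st0, sys$v, sys$edges, sys$v_ij, lambda = 1)
  expect_equal(st0$b, st1$b, tolerance = 1e-12)
})

test_that("an edgeless system reaches softmax marginals in one update", {
  v <- list(c(1, 2, 3), c(-0.5, 0.5))
  ms <- solve_marginals(v, matrix(integer(), 0, 2), list())
  for (i in 1:2) {
    want <- exp(-v[[i]]) / sum(exp(-v[[i]]))
    expect_equal(ms$p[[i]], want, tolerance = 1e-12)
  }
  want_G <- sum(-log(vapply(v, function(x) sum(exp(-x)), numeric(1))))
  expect_equal(ms$G, want_G, tolerance = 1e-12)
})

test_that("belief propagation is exact on trees", {
  set.seed(82)
  for (trial in 1:30) {
    sys <- random_tree_system(sample(3:10, 1))
    ms <- solve_marginals(sys$v, sys$edges, sys$v_ij, tol = 1e-11,
                          max_iter = 5000)
    bf <- brute_force_reference(sys$v, sys$edges, sys$v_ij)
    expect_lt(max(mapply(function(a, b) max(abs(a - b)), ms$p, bf$p)), 1e-6)
    if (length(ms$p_edges))
      expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                           ms$p_edges, bf$p_edges)), 1e-6)
    expect_lt(abs(ms$G - bf$minus_logZ), 1e-6)
  }
})

test_that("free energy shifts by exactly c when one v_i is shifted by c", {
  set.seed(83)
  sys <- random_tree_system(6)
  ms1 <- solve_marginals(sys$v, sys$edges, sys$v_ij, tol = 1e-10)
  v2 <- sys$v
  v2[[3]] <- v2[[3]] + 1.7
  ms2 <- solve_marginals(v2, sys$edges, sys$v_ij, tol = 1e-10)
  expect_equal(ms2$G, ms1$G + 1.7, tolerance = 1e-8)
})

test_that("uniform edgeless marginals give pure entropy -N log n", {
  v <- replicate(4, numeric(3), simplify = FALSE)
  ms <- solve_marginals(v, matrix(integer(), 0, 2), list())
  expect_equal(ms$G, -4 * log(3), tolerance = 1e-12)
})

test_that("repeat runs are bit-identical", {
  set.seed(84)
  sys <- gen_random_field(1, n = 20, states = 3)
  ms1 <- solve_marginals(sys$v, sys$edges, sys$v_ij)
  ms2 <- solve_marginals(sys$v, sys$edges, sys$v_ij)
  expect_identical(ms1$p, ms2$p)
  expect_identical(ms1$G, ms2$G)
})

test_that("converged loopy marginals satisfy the consistency conditions", {
  set.seed(85)
  for (trial in 1:10) {
    sys <- gen_random_field(trial, n = 25, states = 3)
    tol <- 1e-3
    ms <- solve_marginals(sys$v, sys$edges, sys$v_ij, tol = tol)
    if (!ms$converged) next
    cc <- check_consistency(ms$p, ms$p_edges, ms$edges)
    expect_lt(cc$max, 10 * tol)
  }
})

test_that("the perfectly-correlated pair counterexample passes the checks", {
  # Pairwise-consistent marginals that no joint distribution realizes:
  # residues 1-2 and 2-3 perfectly correlated, 1-3 independent.
  p <- replicate(3, rep(1 / 3, 3), simplify = FALSE)
  p_edges <- list(diag(3) / 3, diag(3) / 3, matrix(1 / 9, 3, 3))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  cc <- check_consistency(p, p_edges, edges)
  expect_lt(cc$max, 1e-12)
})

test_that("exact enumeration marginals pass with near-zero violation", {
  set.seed(86)
  sys <- random_tree_system(5)
  bf <- brute_force_reference(sys$v, sys$edges, sys$v_ij)
  cc <- check_consistency(bf$p, bf$p_edges, sys$edges)
  expect_lt(cc$max, 1e-12)
})

test_that("a perturbed pair marginal is reported at its true magnitude", {
  set.seed(87)
  sys <- random_tree_system(4)
  bf <- brute_force_reference(sys$v, sys$edges, sys$v_ij)
  pe <- bf$p_edges
  pe[[1]][1, 1] <- pe[[1]][1, 1] + 0.01
  cc <- check_consistency(bf$p, pe, sys$edges)
  expect_equal(cc$normalization, 0.01, tolerance = 1e-9)
})

test_that("brute force handles single residues and tiny couplings by hand", {
  v <- list(c(0.2, -0.4))
  bf <- brute_force_reference(v, matrix(integer(), 0, 2), list())
  expect_equal(bf$p[[1]], exp(-v[[1]]) / sum(exp(-v[[1]])), tolerance = 1e-12)
  # 2 residues x 2 states: compare against the explicit 4-term sum
  v <- list(c(0, 0.5), c(-0.3, 0.2))
  W <- matrix(c(0.1, -0.2, 0.3, 0), 2, 2)
  bf <- brute_force_reference(v, matrix(c(1L, 2L), 1), list(W))
  Z <- 0
  for (a in 1:2) for (b in 1:2) Z <- Z + exp(-(v[[1]][a] + v[[2]][b] + W[a, b]))
  expect_equal(bf$minus_logZ, -log(Z), tolerance = 1e-12)
  p11 <- exp(-(v[[1]][1] + v[[2]][1] + W[1, 1])) / Z
  expect_equal(bf$p_edges[[1]][1, 1], p11, tolerance = 1e-12)
})

test_that("brute force refuses oversized state spaces", {
  v <- replicate(30, numeric(6), simplify = FALSE)
  expect_error(brute_force_reference(v, matrix(integer(), 0, 2), list()),
               "too large")
})
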