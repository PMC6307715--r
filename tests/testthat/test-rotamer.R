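# Toy three-state single-type library with hand-set weights, used by the
# closed-form coarse-graining checks.
toy_library <- function(w = NULL, positions = NULL, n_chi1 = 1L,
                        spacing_deg = 30) {
  centers <- rama_grid_centers(spacing_deg)
  G <- length(centers)
  nf <- if (is.null(w)) 3L else length(w)
  if (is.null(w)) w <- rep(1 / 3, 3)
  prob <- array(rep(w, G * G), c(nf, G, G))
  atoms <- array(0, c(nf, 1, 3))
  if (is.null(positions)) positions <- cbind(seq_len(nf), 0, 0)
  atoms[, 1, ] <- positions
  fine_rotamer_library(list(TOY = list(
    chi1_bin = rep(1L, nf), chi2_bin = seq_len(nf),
    chi_higher = rep(1L, nf), prob = prob, atoms = atoms,
    n_chi1 = 1L, n_chi2 = nf)), centers)
}

test_that("pooling all fine states gives q = 1 everywhere", {
  lib <- toy_library()
  cs <- coarse_states(lib, rep(1L, 3), "TOY")
  expect_lt(max(abs(cs$q - 1)), 1e-12)
})

test_that("equal-probability states at +/-d average to the midpoint", {
  lib <- toy_library(w = c(0.5, 0.5), positions = rbind(c(-2, 0, 0), c(2, 0, 0)))
  cs <- coarse_states(lib, c(1L, 1L), "TOY")
  expect_lt(max(abs(cs$y[1, 1, 1, , ])), 1e-12)
})

test_that("coarse positions match a direct per-grid-point weighted average", {
  set.seed(31)
  lib <- fixture_library()
  tp <- lib$types$LEU
  nf <- length(tp$chi1_bin)
  mapping <- tp$chi1_bin        # pool by chi1
  cs <- coarse_states(lib, mapping, "LEU")
  G <- length(lib$centers)
  for (trial in 1:20) {
    gi <- sample(G, 1); gj <- sample(G, 1)
    c0 <- sample(max(mapping), 1); a <- sample(dim(tp$atoms)[2], 1)
    fs <- which(mapping == c0)
    w <- tp$prob[fs, gi, gj]
    X <- matrix(tp$atoms[fs, a, ], ncol = 3)
    want <- colSums(w * X) / sum(w)
    expect_lt(max(abs(cs$y[c0, a, , gi, gj] - want)), 1e-12)
  }
})

test_that("singleton coarse states have zero positional error", {
  lib <- toy_library()
  s2 <- partition_error(lib, 1:3, fixture_rama_30(), "TOY")
  expect_lt(as.numeric(s2), 1e-14)
})

test_that("merging identical positions costs nothing", {
  lib <- toy_library(w = c(0.3, 0.7), positions = rbind(c(1, 2, 3), c(1, 2, 3)))
  s2 <- partition_error(lib, c(1L, 1L), fixture_rama_30(), "TOY")
  expect_lt(as.numeric(s2), 1e-14)
})

test_that("two-state merge reproduces the closed form w(1-w)d^2", {
  for (w in c(0.2, 0.5, 0.9)) {
    d <- 3.1
    lib <- toy_library(w = c(w, 1 - w),
                       positions = rbind(c(0, 0, 0), c(d, 0, 0)))
    s2 <- as.numeric(partition_error(lib, c(1L, 1L), fixture_rama_30(), "TOY"))
    expect_equal(s2, w * (1 - w) * d^2, tolerance = 1e-10)
  }
})

test_that("optimizer agrees with the exhaustive set-partition oracle", {
  lib <- gen_rotamer_library(41, types = "LEU", n_chi1 = 2, n_chi2 = 3,
                             spacing_deg = 30)
  rama <- synthetic_rama_density(30)
  tp <- lib$types$LEU
  nf <- length(tp$chi1_bin)
  for (ms in c(3L, 4L)) {
    opt <- optimize_partition(lib, rama, max_states = ms)
    # oracle: all set partitions, filtered to the admissible ones
    best <- Inf
    for (lab in all_set_partitions(nf)) {
      if (max(lab) > ms) next
      ok <- tryCatch({ check_partition_constraints(lib, lab, "LEU"); TRUE },
                     error = function(e) FALSE)
      if (!ok) next
      s2 <- as.numeric(partition_error(lib, lab, rama, "LEU"))
      best <- min(best, s2)
    }
    expect_equal(opt$types$LEU$sigma2, best, tolerance = 1e-12)
  }
})

test_that("minimal error is non-increasing in the state budget", {
  lib <- gen_rotamer_library(42, types = "ARG", n_chi1 = 3, n_chi2 = 3,
                             spacing_deg = 30)
  rama <- synthetic_rama_density(30)
  prev <- Inf
  for (ms in 3:6) {
    s2 <- optimize_partition(lib, rama, max_states = ms)$types$ARG$sigma2
    expect_lte(s2, prev + 1e-15)
    prev <- s2
  }
})

test_that("a chi1-only library is forced to the unique per-bin partition", {
  lib <- gen_rotamer_library(43, types = "VAL", n_chi1 = 3, n_chi2 = 1,
                             spacing_deg = 30)
  opt <- optimize_partition(lib, synthetic_rama_density(30), max_states = 6)
  expect_identical(opt$types$VAL$n_coarse, 3L)
  expect_identical(opt$types$VAL$mapping, lib$types$VAL$chi1_bin)
})

test_that("more chi1 bins than the budget is infeasible", {
  lib <- gen_rotamer_library(44, types = "LYS", n_chi1 = 4, n_chi2 = 1,
                             spacing_deg = 30)
  expect_error(optimize_partition(lib, synthetic_rama_density(30),
                                  max_states = 3), "infeasible")
})

test_that("returned partitions always satisfy the structural constraints", {
  part <- fixture_partition()
  lib <- fixture_library()
  for (nm in names(part$types)) {
    expect_true(check_partition_constraints(lib, part$types[[nm]]$mapping, nm))
    q <- part$types[[nm]]$q
    expect_lt(max(abs(apply(q, c(2, 3), sum) - 1)), 1e-9)
    expect_false(anyNA(part$types[[nm]]$chi1_of_state))
  }
})

test_that("higher-chi splits never separate a (chi1, chi2) bin", {
  lib <- gen_rotamer_library(45, types = "GLU", n_chi1 = 2, n_chi2 = 2,
                             n_higher = 2, spacing_deg = 30)
  opt <- optimize_partition(lib, synthetic_rama_density(30))
  tp <- lib$types$GLU
  key <- paste(tp$chi1_bin, tp$chi2_bin)
  mp <- opt$types$GLU$mapping
  for (k in unique(key))
    expect_identical(length(unique(mp[key == k])), 1L)
})
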