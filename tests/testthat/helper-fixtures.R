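# Shared fixtures, memoized so the suite builds each expensive object once.

.fx <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.fx$lib))
    .fx$lib <- gen_rotamer_library(11, types = c("ALA", "SER", "VAL", "LEU"))
  .fx$lib
}

fixture_rama <- function() {
  if (is.null(.fx$rama)) .fx$rama <- synthetic_rama_density()
  .fx$rama
}

fixture_rama_30 <- function() {
  if (is.null(.fx$rama30)) .fx$rama30 <- synthetic_rama_density(30)
  .fx$rama30
}

fixture_partition <- function() {
  if (is.null(.fx$part))
    .fx$part <- optimize_partition(fixture_library(), fixture_rama())
  .fx$part
}

fixture_params <- function() {
  if (is.null(.fx$params))
    .fx$params <- make_parameter_set(fixture_partition(), fixture_rama())
  .fx$params
}

# Parameters with randomly perturbed spline coefficients, so that the
# directional terms are non-trivial in gradient tests.
fixture_params_perturbed <- function(sd = 0.2, seed = 9) {
  key <- paste0("pp", sd, "_", seed)
  if (is.null(.fx[[key]])) {
    params <- fixture_params()
    th <- flatten_params(params)
    set.seed(seed)
    th <- th + rnorm(length(th), sd = sd)
    .fx[[key]] <- unflatten_params(params, th)
  }
  .fx[[key]]
}

fixture_chain <- function(n = 10, topology = "random", seed = 5,
                          noise_deg = 8) {
  gen_toy_protein(seed, n, topology,
                  types = c("ALA", "SER", "VAL", "LEU"),
                  noise_deg = noise_deg)
}

random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

transform_chain <- function(chain, R, t) {
  chain$N <- sweep(chain$N %*% t(R), 2, t, "+")
  chain$CA <- sweep(chain$CA %*% t(R), 2, t, "+")
  chain$C <- sweep(chain$C %*% t(R), 2, t, "+")
  chain
}

# Random discrete tree-structured system (for BP exactness checks).
random_tree_system <- function(n, max_states = 4L, coupling = 1) {
  ns <- sample(2:max_states, n, replace = TRUE)
  while (prod(ns) > 2e5) ns[which.max(ns)] <- 2L
  edges <- if (n > 1) {
    e <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
    t(apply(e, 1, sort))
  } else matrix(integer(), 0, 2)
  v <- lapply(ns, function(k) rnorm(k))
  v_ij <- lapply(seq_len(nrow(edges)), function(e)
    matrix(rnorm(ns[edges[e, 1]] * ns[edges[e, 2]], sd = coupling),
           ns[edges[e, 1]], ns[edges[e, 2]]))
  list(v = v, edges = edges, v_ij = v_ij, ns = ns)
}

# Independent clamped-spline oracle: solves the full piecewise-cubic
# linear system densely instead of the tridiagonal second-derivative form.
oracle_clamped_spline <- function(coef, x0, h, xq) {
  K <- length(coef)
  np <- K - 1
  # unknowns: a_i, b_i, c_i, d_i per piece: S_i(x) = a + b u + c u^2 + d u^3,
  # u = x - x_i
  A <- matrix(0, 4 * np, 4 * np)
  rhs <- numeric(4 * np)
  row <- 0
  idx <- function(i, k) (i - 1) * 4 + k
  for (i in seq_len(np)) {
    row <- row + 1; A[row, idx(i, 1)] <- 1; rhs[row] <- coef[i]
    row <- row + 1
    A[row, idx(i, 1:4)] <- c(1, h, h^2, h^3); rhs[row] <- coef[i + 1]
  }
  for (i in seq_len(np - 1)) {
    row <- row + 1
    A[row, idx(i, 2:4)] <- c(1, 2 * h, 3 * h^2); A[row, idx(i + 1, 2)] <- -1
    row <- row + 1
    A[row, idx(i, 3:4)] <- c(2, 6 * h); A[row, idx(i + 1, 3)] <- -2
  }
  row <- row + 1; A[row, idx(1, 2)] <- 1              # S'(x0) = 0
  row <- row + 1; A[row, idx(np, 2:4)] <- c(1, 2 * h, 3 * h^2)  # S'(xK) = 0
  sol <- solve(A, rhs)
  vapply(xq, function(x) {
    xi <- min(max(floor((x - x0) / h) + 1, 1), np)
    u <- x - (x0 + (xi - 1) * h)
    cf <- sol[idx(xi, 1:4)]
    cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
  }, numeric(1))
}

# Independent quaternion (Horn) superposition oracle.
oracle_quaternion_frame <- function(X, ref) {
  xbar <- colMeans(X); abar <- colMeans(ref)
  Xc <- sweep(X, 2, xbar); Ac <- sweep(ref, 2, abar)
  S <- t(Ac) %*% Xc
  Kq <- matrix(0, 4, 4)
  Kq[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  Kq[1, 2] <- Kq[2, 1] <- S[2, 3] - S[3, 2]
  Kq[1, 3] <- Kq[3, 1] <- S[3, 1] - S[1, 3]
  Kq[1, 4] <- Kq[4, 1] <- S[1, 2] - S[2, 1]
  Kq[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  Kq[2, 3] <- Kq[3, 2] <- S[1, 2] + S[2, 1]
  Kq[2, 4] <- Kq[4, 2] <- S[1, 3] + S[3, 1]
  Kq[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  Kq[3, 4] <- Kq[4, 3] <- S[2, 3] + S[3, 2]
  Kq[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(Kq, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(rotation = R, translation = as.numeric(xbar - R %*% abar))
}

# All set partitions of seq_len(n) as restricted-growth label vectors.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(lab, mx) {
    k <- length(lab) + 1
    if (k > n) { out[[length(out) + 1L]] <<- lab; return(invisible()) }
    for (b in seq_len(mx + 1)) rec(c(lab, b), max(mx, b))
    invisible()
  }
  rec(integer(0), 0L)
  out
}

# NERF-based oracle placement of O and H on an ideal dipeptide.
oracle_dipeptide_OH <- function(chain) {
  d2r <- pi / 180
  O1 <- nerf_place(chain$N[2, ], chain$CA[1, ], chain$C[1, ],
                   1.229, 120 * d2r, pi)
  H2 <- nerf_place(chain$C[1, ], chain$CA[2, ], chain$N[2, ],
                   1.010, 120 * d2r, pi)
  list(O1 = O1, H2 = H2)
}
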