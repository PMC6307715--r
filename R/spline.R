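# Uniform-knot clamped cubic splines.
#
# All tabulated curves in the potential (radial curves on [0, R_cutoff] with a
# 0.5 A knot spacing, angular curves on [-1, 1] with a 1/6 spacing in cos
# theta) are interpolating cubic splines through the knot values, with the
# first derivative clamped to zero at both ends.  The zero-derivative clamp
# makes every radial curve approach its cutoff smoothly, so the pair energy
# and its gradient vanish continuously as an interaction leaves the graph.
#
# The spline value is a linear function of the knot values,
#   S(x) = sum_k B_k(x) c_k,
# which is what makes maximum-likelihood training cheap: the basis B is
# cached per (n_knots, spacing) and reused for every energy, force and
# parameter-gradient evaluation.

.spline_cache <- new.env(parent = emptyenv())

# Matrix G mapping knot values c to knot second derivatives M = G c for a
# clamped (S' = 0 at both ends) cubic spline on K uniform knots with spacing h.
spline_second_deriv_matrix <- function(K, h) {
  key <- paste0("G:", K, ":", format(h, digits = 17))
  if (!is.null(.spline_cache[[key]])) return(.spline_cache[[key]])
  stopifnot(K >= 2, h > 0)
  A <- matrix(0, K, K)
  D <- matrix(0, K, K)
  # clamped end: (h/3) M_1 + (h/6) M_2 = (c_2 - c_1)/h - S'(x_1), S'(x_1) = 0
  A[1, 1] <- h / 3; A[1, 2] <- h / 6
  D[1, 1] <- -1 / h; D[1, 2] <- 1 / h
  if (K > 2) {
    for (i in 2:(K - 1)) {
      A[i, i - 1] <- h / 6; A[i, i] <- 2 * h / 3; A[i, i + 1] <- h / 6
      D[i, i - 1] <- 1 / h; D[i, i] <- -2 / h; D[i, i + 1] <- 1 / h
    }
  }
  A[K, K - 1] <- h / 6; A[K, K] <- h / 3
  D[K, K - 1] <- 1 / h; D[K, K] <- -1 / h
  G <- solve(A, D)
  .spline_cache[[key]] <- G
  G
}

# Locate interval indices for points x on knots x0 + (0:(K-1)) * h.
.spline_interval <- function(x, x0, h, K) {
  i <- floor((x - x0) / h) + 1L
  pmin.int(pmax.int(i, 1L), K - 1L)
}

#' Evaluate a clamped cubic spline through uniform knot values
#'
#' @param coef numeric vector of knot values (length K).
#' @param x0 position of the first knot.
#' @param h knot spacing (> 0).
#' @param x points at which to evaluate.
#' @param deriv 0 for the value, 1 for the first derivative in `x`.
#' @param clamp_below if TRUE, points below `x0` evaluate as at `x0`
#'   (flat extension, consistent with the zero-derivative clamp).
#' @param zero_above if TRUE, points at or beyond the last knot return 0
#'   (radial curves vanish at the cutoff); otherwise they extend flat.
#' @return numeric vector of spline values or derivatives.
#' @export
spline_eval <- function(coef, x0, h, x, deriv = 0L, clamp_below = TRUE,
                        zero_above = FALSE) {
  K <- length(coef)
  G <- spline_second_deriv_matrix(K, h)
  M <- as.numeric(G %*% coef)
  xmax <- x0 + (K - 1) * h
  out <- numeric(length(x))
  above <- x >= xmax - 1e-12
  xe <- x
  if (clamp_below) xe <- pmax(xe, x0)
  xe <- pmin(xe, xmax)
  i <- .spline_interval(xe, x0, h, K)
  xl <- x0 + (i - 1) * h
  A <- (xl + h - xe) / h
  B <- (xe - xl) / h
  if (deriv == 0L) {
    out <- A * coef[i] + B * coef[i + 1L] +
      ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1L]) * h^2 / 6
  } else {
    out <- (coef[i + 1L] - coef[i]) / h +
      (-(3 * A^2 - 1) * M[i] + (3 * B^2 - 1) * M[i + 1L]) * h / 6
  }
  if (zero_above) out[above] <- 0
  else if (deriv == 1L) out[above] <- 0
  if (clamp_below && deriv == 1L) out[x < x0] <- 0
  out
}

#' Basis matrix of a clamped cubic spline in its knot values
#'
#' Returns the matrix `B` with `S(x) = B %*% coef`, exploiting that an
#' interpolating spline is linear in its knot values.
#'
#' @inheritParams spline_eval
#' @param K number of knots.
#' @return `length(x)` x `K` matrix.
#' @export
spline_basis <- function(K, x0, h, x, clamp_below = TRUE, zero_above = FALSE) {
  G <- spline_second_deriv_matrix(K, h)
  xmax <- x0 + (K - 1) * h
  above <- x >= xmax - 1e-12
  xe <- x
  if (clamp_below) xe <- pmax(xe, x0)
  xe <- pmin(xe, xmax)
  i <- .spline_interval(xe, x0, h, K)
  xl <- x0 + (i - 1) * h
  A <- (xl + h - xe) / h
  Bf <- (xe - xl) / h
  n <- length(x)
  W <- matrix(0, n, K)           # direct knot-value part
  WM <- matrix(0, n, K)          # weight on the second derivatives
  idx <- cbind(seq_len(n), i)
  idx2 <- cbind(seq_len(n), i + 1L)
  W[idx] <- A
  W[idx2] <- W[idx2] + Bf
  WM[idx] <- (A^3 - A) * h^2 / 6
  WM[idx2] <- WM[idx2] + (Bf^3 - Bf) * h^2 / 6
  B <- W + WM %*% G
  if (zero_above && any(above)) B[above, ] <- 0
  B
}
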