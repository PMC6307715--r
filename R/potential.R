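# The oriented-bead pair potential and the backbone hydrogen-bond
# confidence score.  Each interaction pair carries four clamped cubic
# splines: an isotropic radial curve V_radial(r), a directional radial
# envelope V_angular(r), and two angular factors ang1/ang2 in cos(theta).
# The energy of a pair of oriented beads is
#   E = kappa * ( V_radial(r12) + ang1(-n1.n12) * ang2(n2.n12) * V_angular(r12) )
# in units of kT, with n12 = (y1 - y2)/r12, vanishing smoothly at the
# cutoff.  kappa is 1 except for side chain-O/H interactions, where it is
# 1 - f with f the hydrogen-bond confidence of the backbone site.

RADIAL_SPACING <- 0.5            # Angstrom between radial knots
ANGULAR_KNOTS <- 13L             # knots on [-1, 1]: spacing 1/6 in cos(theta)

radial_knot_count <- function(cutoff) as.integer(round(cutoff / RADIAL_SPACING)) + 1L
angular_spacing <- function() 2 / (ANGULAR_KNOTS - 1)

#' Default spline block for one interaction pair
#'
#' Radial knots run from 0 to the cutoff at 0.5 A spacing with the last knot
#' pinned to zero; the angular factors are stored as log-coefficients
#' (positivity by exponential transform) and initialized to 1.
#'
#' @param cutoff interaction cutoff in Angstrom.
#' @param directional include the directional (angular) term.
#' @return list with `radial`, `angular`, `ang1`, `ang2`, `cutoff`,
#'   `directional`.
#' @export
default_pair_params <- function(cutoff, directional = TRUE) {
  K <- radial_knot_count(cutoff)
  r <- seq(0, cutoff, length.out = K)
  radial <- 5 * pmax(0, 1 - r / 3)^2       # repulsive core, 5 kT at contact
  radial[K] <- 0
  list(radial = radial,
       angular = numeric(K),
       ang1 = numeric(ANGULAR_KNOTS),      # log-coefficients, exp() = 1
       ang2 = numeric(ANGULAR_KNOTS),
       cutoff = cutoff, directional = directional)
}

#' Oriented-bead pair energy
#'
#' @param y1,y2 bead positions (3-vectors, Angstrom).
#' @param n1,n2 unit direction vectors (may be NULL for an isotropic site,
#'   in which case the directional term is dropped).
#' @param pp spline block from [default_pair_params()] (or trained values).
#' @param kappa scalar prefactor (hydrogen-bond gating; 1 for side
#'   chain-side chain terms).
#' @return energy in kT; exactly 0 at and beyond the cutoff.
#' @export
pair_energy <- function(y1, n1, y2, n2, pp, kappa = 1) {
  pair_energy_full(y1, n1, y2, n2, pp, kappa, grad = FALSE, basis = FALSE)$value
}

# Full evaluation: value, gradients with respect to positions/directions,
# and (optionally) the basis rows for the trainable spline coefficients.
pair_energy_full <- function(y1, n1, y2, n2, pp, kappa = 1,
                             grad = FALSE, basis = FALSE) {
  d <- y1 - y2
  r <- sqrt(sum(d * d))
  if (r == 0) stop("coincident interaction sites (r = 0)")
  K <- length(pp$radial)
  out <- list(value = 0, unit_value = 0)
  if (r >= pp$cutoff) {
    if (grad) {
      out$dy1 <- out$dy2 <- numeric(3)
      out$dn1 <- out$dn2 <- numeric(3)
    }
    if (basis) {
      out$b_radial <- numeric(K)
      out$b_angular <- numeric(K)
      out$b_ang1 <- numeric(ANGULAR_KNOTS)
      out$b_ang2 <- numeric(ANGULAR_KNOTS)
    }
    return(out)
  }
  h <- RADIAL_SPACING
  ha <- angular_spacing()
  u <- d / r
  vr <- spline_eval(pp$radial, 0, h, r, zero_above = TRUE)
  dir_on <- isTRUE(pp$directional) && !is.null(n1) && !is.null(n2)
  if (dir_on) {
    x1 <- max(-1, min(1, -sum(n1 * u)))
    x2 <- max(-1, min(1, sum(n2 * u)))
    c1 <- exp(pp$ang1); c2 <- exp(pp$ang2)
    a1 <- spline_eval(c1, -1, ha, x1)
    a2 <- spline_eval(c2, -1, ha, x2)
    va <- spline_eval(pp$angular, 0, h, r, zero_above = TRUE)
    E0 <- vr + a1 * a2 * va
  } else {
    E0 <- vr
  }
  out$unit_value <- E0
  out$value <- kappa * E0
  if (grad) {
    dvr <- spline_eval(pp$radial, 0, h, r, deriv = 1L, zero_above = TRUE)
    if (dir_on) {
      dva <- spline_eval(pp$angular, 0, h, r, deriv = 1L, zero_above = TRUE)
      da1 <- spline_eval(c1, -1, ha, x1, deriv = 1L)
      da2 <- spline_eval(c2, -1, ha, x2, deriv = 1L)
      Pu <- (diag(3) - tcrossprod(u)) / r
      dx1_dy1 <- as.numeric(-(n1 %*% Pu))
      dx2_dy1 <- as.numeric(n2 %*% Pu)
      dE_dy1 <- (dvr + a1 * a2 * dva) * u +
        va * (da1 * a2 * dx1_dy1 + a1 * da2 * dx2_dy1)
      out$dy1 <- kappa * dE_dy1
      out$dy2 <- -out$dy1
      out$dn1 <- kappa * va * a2 * da1 * (-u)
      out$dn2 <- kappa * va * a1 * da2 * u
    } else {
      out$dy1 <- kappa * dvr * u
      out$dy2 <- -out$dy1
      out$dn1 <- out$dn2 <- numeric(3)
    }
  }
  if (basis) {
    out$r <- r
    out$x1 <- if (dir_on) x1 else NA_real_
    out$x2 <- if (dir_on) x2 else NA_real_
    out$b_radial <- kappa * as.numeric(spline_basis(K, 0, h, r, zero_above = TRUE))
    if (dir_on) {
      Ba <- as.numeric(spline_basis(K, 0, h, r, zero_above = TRUE))
      B1 <- as.numeric(spline_basis(ANGULAR_KNOTS, -1, ha, x1))
      B2 <- as.numeric(spline_basis(ANGULAR_KNOTS, -1, ha, x2))
      out$b_angular <- kappa * a1 * a2 * Ba
      out$b_ang1 <- kappa * a2 * va * B1 * c1    # d/d(log coef) = B * exp(t)
      out$b_ang2 <- kappa * a1 * va * B2 * c2
    } else {
      out$b_angular <- numeric(K)
      out$b_ang1 <- numeric(ANGULAR_KNOTS)
      out$b_ang2 <- numeric(ANGULAR_KNOTS)
    }
  }
  out
}

# cubic smoothstep on [0, 1]
.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}
.smoothstep_d <- function(x) {
  ifelse(x <= 0 | x >= 1, 0, 6 * x * (1 - x))
}

default_hbond_criteria <- function() {
  list(r_on = 1.4, r_off = 2.5,                 # H...O distance window (A)
       r_width = 0.3,                           # smooth transition width (A)
       cos_half = cos(47 * pi / 180))           # angular half-height
}

#' Backbone hydrogen-bond confidence score
#'
#' A smooth score in \code{[0, 1]} for an N-H...O=C geometry: the product of
#' a distance switch on the H...O separation (on below 1.4 A, off at 2.5 A)
#' and two angular switches on the N-H-O and H-O-C alignments whose
#' half-heights sit 47 degrees off co-linear.
#'
#' @param H,O donor hydrogen and acceptor oxygen positions; if either is
#'   NULL or non-finite the score is 0 (no hydrogen bond possible).
#' @param N donor nitrogen position; `C` acceptor carbonyl carbon.
#' @param criteria list of switch constants (see `default_hbond_criteria`).
#' @param grad if TRUE, attach gradients with respect to the four atoms.
#' @return scalar f in \code{[0, 1]}; with `grad`, a list with `value` and
#'   3-vector gradients `dH`, `dO`, `dN`, `dC`.
#' @export
hbond_confidence <- function(H, O, N, C, criteria = default_hbond_criteria(),
                             grad = FALSE) {
  zero <- if (grad) list(value = 0, dH = numeric(3), dO = numeric(3),
                         dN = numeric(3), dC = numeric(3)) else 0
  if (is.null(H) || is.null(O) || is.null(N) || is.null(C)) return(zero)
  if (any(!is.finite(c(H, O, N, C)))) return(zero)
  cr <- criteria
  w <- if (is.null(cr$r_width)) 0.3 else cr$r_width
  dHO <- O - H
  r <- vnorm(dHO)
  # distance window: on across [r_on, r_on + w], plateau, off at r_off
  t_up <- (r - cr$r_on) / w
  t_dn <- (r - (cr$r_off - w)) / w
  s_up <- .smoothstep(t_up); s_dn <- 1 - .smoothstep(t_dn)
  sd_ <- s_up * s_dn
  if (sd_ == 0) return(zero)
  a <- 2 * cr$cos_half - 1                      # switch support in cos(theta)
  uNH <- unit3(H - N)
  uHO <- unit3(O - H)
  uOC <- unit3(C - O)
  x1 <- sum(uNH * uHO)                          # 1 when N-H-O co-linear
  x2 <- sum(uHO * uOC)                          # 1 when H-O-C co-linear
  t1 <- (x1 - a) / (1 - a)
  t2 <- (x2 - a) / (1 - a)
  s1 <- .smoothstep(t1); s2 <- .smoothstep(t2)
  f <- sd_ * s1 * s2
  if (!grad) return(f)
  # gradients
  dsd_dr <- .smoothstep_d(t_up) / w * s_dn - s_up * .smoothstep_d(t_dn) / w
  ds1 <- .smoothstep_d(t1) / (1 - a)
  ds2 <- .smoothstep_d(t2) / (1 - a)
  ur <- dHO / r
  DNH <- d_unit(H - N); DHO <- d_unit(O - H); DOC <- d_unit(C - O)
  # x1 = uNH . uHO ; x2 = uHO . uOC
  dx1 <- list(N = -as.numeric(uHO %*% DNH),
              H = as.numeric(uHO %*% DNH) - as.numeric(uNH %*% DHO),
              O = as.numeric(uNH %*% DHO), C = numeric(3))
  dx2 <- list(N = numeric(3),
              H = -as.numeric(uOC %*% DHO),
              O = as.numeric(uOC %*% DHO) - as.numeric(uHO %*% DOC),
              C = as.numeric(uHO %*% DOC))
  dr <- list(N = numeric(3), H = -ur, O = ur, C = numeric(3))
  g <- lapply(c(N = "N", H = "H", O = "O", C = "C"), function(nm) {
    dsd_dr * dr[[nm]] * s1 * s2 + sd_ * ds1 * dx1[[nm]] * s2 +
      sd_ * s1 * ds2 * dx2[[nm]]
  })
  list(value = f, dH = g$H, dO = g$O, dN = g$N, dC = g$C)
}
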