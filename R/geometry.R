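# Backbone geometry: chain representation, deterministic O/H placement,
# per-residue rigid frames (least-RMSD superposition) and oriented-bead
# placement, all with analytic Jacobians so forces on derived sites can be
# pulled back onto the N/CA/C atoms exactly.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

vnorm <- function(v) sqrt(sum(v * v))
unit3 <- function(v) v / vnorm(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
skew3 <- function(v) matrix(c(0, v[3], -v[2],
                              -v[3], 0, v[1],
                              v[2], -v[1], 0), 3, 3)
# Jacobian of v/|v| with respect to v
d_unit <- function(v) {
  n <- vnorm(v)
  u <- v / n
  (diag(3) - tcrossprod(u)) / n
}

#' Construct and validate a backbone chain
#'
#' A reduced protein representation holding, per residue, the three backbone
#' trace atoms N, CA and C (coordinates in Angstrom) plus the residue type.
#'
#' @param residues character vector of three-letter residue types.
#' @param N,CA,C numeric n x 3 coordinate matrices.
#' @param chain_id single chain identifier.
#' @return an object of class `backbone_chain`.
#' @export
backbone_chain <- function(residues, N, CA, C, chain_id = "A") {
  N <- rbind(N); CA <- rbind(CA); C <- rbind(C)
  n <- length(residues)
  if (n < 1) stop("backbone_chain needs at least one residue")
  if (nrow(N) != n || nrow(CA) != n || nrow(C) != n)
    stop("coordinate matrices must have one row per residue")
  if (!all(is.finite(N)) || !all(is.finite(CA)) || !all(is.finite(C)))
    stop("non-finite backbone coordinates")
  if (n > 1) {
    dcn <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    if (any(!is.finite(dcn)) || any(dcn <= 0))
      stop("consecutive C->N distances must be finite and positive")
  }
  structure(list(residues = as.character(residues), N = N, CA = CA, C = C,
                 chain_id = chain_id),
            class = "backbone_chain")
}

#' @export
length.backbone_chain <- function(x) length(x$residues)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("backbone_chain: %d residues, chain %s\n",
              length(x$residues), x$chain_id))
  invisible(x)
}

#' Flatten / restore backbone coordinates
#'
#' `chain_coords` returns the flat coordinate vector in (N, CA, C) atom
#' order per residue — the layout used by forces and the integrator;
#' `chain_from_coords` writes such a vector back into a chain.
#'
#' @param chain a [backbone_chain()].
#' @return numeric vector of length `9 * n_residues`.
#' @export
chain_coords <- function(chain) {
  n <- length(chain$residues)
  x <- matrix(0, 3 * n, 3)
  x[seq(1, 3 * n, 3), ] <- chain$N
  x[seq(2, 3 * n, 3), ] <- chain$CA
  x[seq(3, 3 * n, 3), ] <- chain$C
  as.numeric(t(x))
}

#' @rdname chain_coords
#' @param coords flat coordinate vector from `chain_coords`.
#' @export
chain_from_coords <- function(chain, coords) {
  n <- length(chain$residues)
  x <- matrix(coords, ncol = 3, byrow = TRUE)
  chain$N <- x[seq(1, 3 * n, 3), , drop = FALSE]
  chain$CA <- x[seq(2, 3 * n, 3), , drop = FALSE]
  chain$C <- x[seq(3, 3 * n, 3), , drop = FALSE]
  chain
}

# Global coordinate indices (into the flat vector) of atom `which` of residue i
atom_cidx <- function(i, which) {
  a <- (i - 1L) * 3L + match(which, c("N", "CA", "C"))
  (a - 1L) * 3L + 1:3
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in radians in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Gradient of the dihedral with respect to the four points (3 x 4 matrix).
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  nb2 <- vnorm(b2)
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  g1 <- nb2 / sum(n1 * n1) * n1
  g4 <- -nb2 / sum(n2 * n2) * n2
  c12 <- sum(b1 * b2) / sum(b2 * b2)
  c32 <- sum(b3 * b2) / sum(b2 * b2)
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  cbind(g1, g2, g3, g4)
}

#' Place an atom from internal coordinates (NERF construction)
#'
#' Places D from atoms A, B, C given the bond length |C-D|, the bond angle
#' B-C-D and the torsion A-B-C-D.
#'
#' @param A,B,C numeric 3-vectors.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in radians.
#' @param torsion dihedral in radians.
#' @return numeric 3-vector.
#' @export
nerf_place <- function(A, B, C, bond, angle, torsion) {
  bc <- unit3(C - B)
  w <- cross3(B - A, C - B)
  n <- unit3(w)
  m <- cross3(n, bc)
  C + bond * (-cos(angle) * bc + sin(angle) * (cos(torsion) * m - sin(torsion) * n))
}

# Jacobians of nerf_place with respect to A, B, C (list of three 3x3 matrices).
nerf_jacobian <- function(A, B, C, bond, angle, torsion) {
  v <- C - B; u <- B - A
  bc <- unit3(v)
  w <- cross3(u, v)
  n <- unit3(w)
  m <- cross3(n, bc)
  ca <- cos(angle); sa <- sin(angle)
  ct <- cos(torsion); st <- -sin(torsion)
  Dbc <- d_unit(v); Dn <- d_unit(w)
  # w = u x v with u = B - A, v = C - B:
  # d(u x v)/du = -[v]x, d(u x v)/dv = [u]x; du/dA = -I, du/dB = I, dv/dB = -I
  dw <- list(A = skew3(v),
             B = -skew3(v) - skew3(u),
             C = skew3(u))
  dbc <- list(A = matrix(0, 3, 3), B = -Dbc, C = Dbc)
  out <- vector("list", 3)
  names(out) <- c("A", "B", "C")
  for (nm in names(out)) {
    dn_ <- Dn %*% dw[[nm]]
    dm_ <- -skew3(bc) %*% dn_ + skew3(n) %*% dbc[[nm]]
    J <- bond * (-ca * dbc[[nm]] + sa * (ct * dm_ + st * dn_))
    if (nm == "C") J <- J + diag(3)
    out[[nm]] <- J
  }
  out
}

#' Ideal N/CA/C reference triple
#'
#' Reference backbone coordinates at ideal bond lengths (N-CA 1.453 A,
#' CA-C 1.526 A) and tetrahedral N-CA-C angle (109.5 deg), CA at the origin.
#'
#' @return 3 x 3 matrix with rows N, CA, C.
#' @export
ideal_ncac_reference <- function() {
  ang <- 109.5 * pi / 180
  N <- c(1.453, 0, 0)
  CA <- c(0, 0, 0)
  C <- 1.526 * c(cos(ang), sin(ang), 0)
  unname(rbind(N, CA, C))
}

default_geometry_params <- function() {
  list(O_bond = 1.229, H_bond = 1.010,
       virtN_bond = 1.300, virtN_angle = 120 * pi / 180,
       virtN_torsion = pi,
       reference_ncac = ideal_ncac_reference())
}

#' Deterministically place carbonyl O and amide H atoms
#'
#' O is placed in the CA_i, C_i, N_{i+1} plane on the external bisector of
#' the CA-C-N angle (C=O 1.229 A); for the last residue a virtual next N is
#' extrapolated at ideal geometry.  H is placed in the C_{i-1}, N_i, CA_i
#' plane on the external bisector of the C-N-CA angle (N-H 1.010 A).  The
#' first residue and prolines carry no H.
#'
#' @param chain a [backbone_chain()].
#' @param geometry_params internal-coordinate constants; see
#'   `default_geometry_params` entries `O_bond`, `H_bond`, `virtN_*`.
#' @return list with n x 3 matrices `O` and `H` (NA rows where absent).
#' @export
place_peptide_atoms <- function(chain, geometry_params = default_geometry_params()) {
  n <- length(chain$residues)
  O <- matrix(NA_real_, n, 3)
  H <- matrix(NA_real_, n, 3)
  gp <- geometry_params
  for (i in seq_len(n)) {
    N1 <- if (i < n) chain$N[i + 1, ] else
      nerf_place(chain$N[i, ], chain$CA[i, ], chain$C[i, ],
                 gp$virtN_bond, gp$virtN_angle, gp$virtN_torsion)
    u1 <- unit3(chain$CA[i, ] - chain$C[i, ])
    u2 <- unit3(N1 - chain$C[i, ])
    O[i, ] <- chain$C[i, ] - gp$O_bond * unit3(u1 + u2)
    if (i > 1 && chain$residues[i] != "PRO") {
      w1 <- unit3(chain$C[i - 1, ] - chain$N[i, ])
      w2 <- unit3(chain$CA[i, ] - chain$N[i, ])
      H[i, ] <- chain$N[i, ] - gp$H_bond * unit3(w1 + w2)
    }
  }
  list(O = O, H = H)
}

# Jacobians of the derived O/H atoms with respect to their defining backbone
# coordinates.  Returns per residue a list(O = list(idx, J), H = list(idx, J))
# where idx are flat coordinate indices and J is 3 x length(idx).
derived_atom_jacobians <- function(chain, geometry_params = default_geometry_params()) {
  n <- length(chain$residues)
  gp <- geometry_params
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- list(O = NULL, H = NULL)
    # --- O from CA_i, C_i, N_{i+1} (or virtual N from N_i, CA_i, C_i)
    CAi <- chain$CA[i, ]; Ci <- chain$C[i, ]
    if (i < n) {
      N1 <- chain$N[i + 1, ]
      idx <- c(atom_cidx(i, "CA"), atom_cidx(i, "C"), atom_cidx(i + 1, "N"))
      dN1 <- list(CA = matrix(0, 3, 3), C = matrix(0, 3, 3), X = diag(3))
    } else {
      N1 <- nerf_place(chain$N[i, ], CAi, Ci,
                       gp$virtN_bond, gp$virtN_angle, gp$virtN_torsion)
      Jv <- nerf_jacobian(chain$N[i, ], CAi, Ci,
                          gp$virtN_bond, gp$virtN_angle, gp$virtN_torsion)
      idx <- c(atom_cidx(i, "CA"), atom_cidx(i, "C"), atom_cidx(i, "N"))
      dN1 <- list(CA = Jv$B, C = Jv$C, X = Jv$A)  # X slot = N_i here
    }
    v1 <- CAi - Ci; v2 <- N1 - Ci
    u1 <- unit3(v1); u2 <- unit3(v2)
    s <- u1 + u2
    Du <- d_unit(s)
    D1 <- d_unit(v1); D2 <- d_unit(v2)
    # O = C - L * unit(unit(CA-C) + unit(N1-C)); chain rule per defining atom
    JCA <- -gp$O_bond * Du %*% (D1 %*% diag(3) + D2 %*% dN1$CA)
    JC <- diag(3) - gp$O_bond * Du %*% (D1 %*% (-diag(3)) + D2 %*% (dN1$C - diag(3)))
    JX <- -gp$O_bond * Du %*% (D2 %*% dN1$X)
    res$O <- list(idx = idx, J = cbind(JCA, JC, JX))
    # --- H from C_{i-1}, N_i, CA_i
    if (i > 1 && chain$residues[i] != "PRO") {
      Cp <- chain$C[i - 1, ]; Ni <- chain$N[i, ]
      w1v <- Cp - Ni; w2v <- CAi - Ni
      Dw <- d_unit(unit3(w1v) + unit3(w2v))
      E1 <- d_unit(w1v); E2 <- d_unit(w2v)
      idxH <- c(atom_cidx(i - 1, "C"), atom_cidx(i, "N"), atom_cidx(i, "CA"))
      JCp <- -gp$H_bond * Dw %*% (E1 %*% diag(3))
      JN <- diag(3) - gp$H_bond * Dw %*% (E1 %*% (-diag(3)) + E2 %*% (-diag(3)))
      JCA2 <- -gp$H_bond * Dw %*% (E2 %*% diag(3))
      res$H <- list(idx = idxH, J = cbind(JCp, JN, JCA2))
    }
    out[[i]] <- res
  }
  out
}

#' Least-RMSD rigid frame from a reference triple onto N, CA, C
#'
#' Returns the rigid transform (rotation, translation) that superposes the
#' reference N/CA/C triple onto the observed atoms with minimal RMSD
#' (Kabsch algorithm via SVD).
#'
#' @param N,CA,C observed 3-vectors.
#' @param reference 3 x 3 matrix of reference coordinates (rows N, CA, C).
#' @return list with `rotation` (3 x 3, det +1) and `translation` (3-vector);
#'   a reference point `a` maps to `rotation %*% a + translation`.
#' @export
residue_frame <- function(N, CA, C, reference = ideal_ncac_reference()) {
  X <- rbind(N, CA, C)
  if (vnorm(cross3(CA - N, C - N)) < 1e-8)
    stop("degenerate (collinear) backbone triple")
  abar <- colMeans(reference)
  xbar <- colMeans(X)
  Ac <- sweep(reference, 2, abar)
  Xc <- sweep(X, 2, xbar)
  M <- t(Xc) %*% Ac
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, translation = as.numeric(xbar - R %*% abar),
       M = M, abar = abar, Ac = Ac)
}

# Analytic derivative of the Kabsch frame.  For a unit perturbation e of
# target atom m, the rotation perturbs as dR = R [omega]_x with
# ((tr S) I - S) omega = axial(R^T dM - dM^T R),  S = R^T M (symmetric),
# dM = e a_m^T (a centered).  Returns a function(m, e) -> list(omega, dt).
frame_differential <- function(frame) {
  R <- frame$rotation
  S <- t(R) %*% frame$M
  S <- (S + t(S)) / 2
  Gm <- sum(diag(S)) * diag(3) - S
  Gi <- tryCatch(solve(Gm), error = function(e)
    stop("degenerate frame: rotation derivative undefined"))
  Ac <- frame$Ac
  abar <- frame$abar
  function(m, e) {
    dM <- tcrossprod(e, Ac[m, ])
    K <- t(R) %*% dM
    K <- K - t(K)
    omega <- as.numeric(Gi %*% c(K[3, 2], K[1, 3], K[2, 1]))
    # t = xbar - R abar, so dt = e/3 - R (omega x abar)
    list(omega = omega,
         dt = e / 3 - as.numeric(R %*% cross3(omega, abar)))
  }
}

#' Place an oriented side-chain bead in a residue frame
#'
#' Applies a rigid frame to the stored reference bead position and direction
#' for a (residue type, coarse state) pair.
#'
#' @param frame rigid frame from [residue_frame()].
#' @param residue_type three-letter residue type.
#' @param state coarse-state index (1-based).
#' @param params a parameter set holding `$types[[residue_type]]$bead_pos`
#'   and `$bead_dir` (n_states x 3 matrices in the reference frame).
#' @return list with `position` (3-vector) and `direction` (unit 3-vector).
#' @export
bead_placement <- function(frame, residue_type, state, params) {
  tp <- params$types[[residue_type]]
  if (is.null(tp)) stop("unknown residue type: ", residue_type)
  if (state < 1 || state > nrow(tp$bead_pos))
    stop("state index out of range for ", residue_type)
  pos <- as.numeric(frame$rotation %*% tp$bead_pos[state, ] + frame$translation)
  dir <- as.numeric(frame$rotation %*% tp$bead_dir[state, ])
  list(position = pos, direction = dir / vnorm(dir))
}

# phi/psi dihedrals of every residue (NA at termini).
chain_dihedrals <- function(chain) {
  n <- length(chain$residues)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral_angle(chain$C[i - 1, ], chain$N[i, ],
                               chain$CA[i, ], chain$C[i, ])
    if (i < n)
      psi[i] <- dihedral_angle(chain$N[i, ], chain$CA[i, ],
                               chain$C[i, ], chain$N[i + 1, ])
  }
  list(phi = phi, psi = psi)
}

#' Radius of gyration of the CA trace
#'
#' @param chain a [backbone_chain()].
#' @return numeric scalar in Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  x <- sweep(chain$CA, 2, colMeans(chain$CA))
  sqrt(mean(rowSums(x^2)))
}
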