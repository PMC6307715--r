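# Fine rotamer libraries and their optimized aggregation into at most six
# coarse states.  A fine state f carries chi-bin labels, a backbone-dihedral
# dependent probability p^f(phi, psi) tabulated on a square grid, and side
# chain atom positions x^f.  A coarse partition c(f) pools fine states into
# coarse states; it is scored by the Ramachandran-weighted positional
# variance of the atoms within each coarse state and optimized by complete
# enumeration of the admissible partitions.

#' Ramachandran density on a square (phi, psi) grid
#'
#' @param density G x G matrix of non-negative values over grid cell centers
#'   (phi along rows, psi along columns); normalized on construction.
#' @param centers grid cell centers in radians, shared by phi and psi
#'   (default: 10-degree cells covering [-pi, pi)).
#' @return object of class `rama_density` with the density integrating to 1
#'   under the midpoint rule.
#' @export
rama_density <- function(density, centers = rama_grid_centers()) {
  delta <- centers[2] - centers[1]
  if (any(density < 0)) stop("negative Ramachandran density")
  z <- sum(density) * delta^2
  if (z <= 0) stop("Ramachandran density must have positive mass")
  structure(list(density = density / z, centers = centers, delta = delta),
            class = "rama_density")
}

#' Default (phi, psi) grid cell centers (10-degree spacing)
#' @param spacing_deg grid spacing in degrees.
#' @return numeric vector of cell centers in radians.
#' @export
rama_grid_centers <- function(spacing_deg = 10) {
  d <- spacing_deg * pi / 180
  seq(-pi + d / 2, pi - d / 2, by = d)
}

#' Construct and validate a fine rotamer library
#'
#' @param types named list; each element describes one residue type with
#'   fields `chi1_bin`, `chi2_bin`, `chi_higher` (integer labels per fine
#'   state), `prob` (array `n_fine x G x G` of state probabilities per grid
#'   point, summing to 1 over states), `atoms` (array `n_fine x n_atom x 3`
#'   of positions in the residue frame, or `n_fine x n_atom x 3 x G x G`),
#'   `n_chi1`, `n_chi2`.
#' @param centers grid cell centers (radians) shared by phi and psi.
#' @return object of class `fine_rotamer_library`.
#' @export
fine_rotamer_library <- function(types, centers = rama_grid_centers()) {
  G <- length(centers)
  for (nm in names(types)) {
    tp <- types[[nm]]
    nf <- length(tp$chi1_bin)
    stopifnot(length(tp$chi2_bin) == nf, dim(tp$prob)[1] == nf,
              dim(tp$prob)[2] == G, dim(tp$prob)[3] == G)
    if (any(tp$prob < 0)) stop("negative fine-state probability in ", nm)
    s <- apply(tp$prob, c(2, 3), sum)
    if (max(abs(s - 1)) > 1e-9)
      stop("fine-state probabilities do not sum to 1 at every grid point in ", nm)
    if (is.null(tp$chi_higher)) types[[nm]]$chi_higher <- rep(1L, nf)
  }
  structure(list(types = types, centers = centers,
                 delta = centers[2] - centers[1]),
            class = "fine_rotamer_library")
}

# Atom positions of fine state f at grid point (gi, gj): n_atom x 3
.fine_atoms <- function(tp, f, gi, gj) {
  if (length(dim(tp$atoms)) == 3L) tp$atoms[f, , , drop = TRUE]
  else tp$atoms[f, , , gi, gj, drop = TRUE]
}

#' Coarse-grain fine rotamer states under a given partition
#'
#' Pools fine-state probabilities (`q^c = sum_{f in c} p^f`) and forms the
#' probability-weighted mean atom positions per coarse state and grid point.
#'
#' @param library a [fine_rotamer_library()].
#' @param mapping integer vector `c(f)`: coarse index per fine state.
#' @param type residue type name (default: first type in the library).
#' @return list with `mapping`, `n_coarse`, `q` (`n_c x G x G`), `y`
#'   (`n_c x n_atom x 3 x G x G`), `chi1_of_state`, and `zero_q` flags for
#'   grid points where a coarse state has zero probability (there `y` is the
#'   unweighted mean).
#' @export
coarse_states <- function(library, mapping, type = names(library$types)[1]) {
  tp <- library$types[[type]]
  nf <- length(tp$chi1_bin)
  if (length(mapping) != nf) stop("mapping must cover all fine states")
  nc <- max(mapping)
  if (!setequal(unique(mapping), seq_len(nc)))
    stop("empty coarse state in mapping")
  G <- length(library$centers)
  na <- dim(tp$atoms)[2]
  q <- array(0, c(nc, G, G))
  y <- array(0, c(nc, na, 3, G, G))
  zero_q <- array(FALSE, c(nc, G, G))
  const_atoms <- length(dim(tp$atoms)) == 3L
  for (c0 in seq_len(nc)) {
    fs <- which(mapping == c0)
    pc <- tp$prob[fs, , , drop = FALSE]
    qc <- apply(pc, c(2, 3), sum)
    q[c0, , ] <- qc
    zero_q[c0, , ] <- qc <= 0
    if (const_atoms) {
      X <- tp$atoms[fs, , , drop = FALSE]        # nfs x na x 3
      for (a in seq_len(na)) for (d in 1:3) {
        # weighted mean over fine states; broadcast X over grid
        w <- matrix(0, G, G)
        for (k in seq_along(fs)) w <- w + pc[k, , ] * X[k, a, d]
        m <- ifelse(qc > 0, w / pmax(qc, .Machine$double.xmin),
                    mean(X[, a, d]))
        y[c0, a, d, , ] <- m
      }
    } else {
      for (gi in seq_len(G)) for (gj in seq_len(G)) {
        w <- pc[, gi, gj]
        Xg <- tp$atoms[fs, , , gi, gj, drop = FALSE]
        dim(Xg) <- c(length(fs), na, 3)
        for (a in seq_len(na)) for (d in 1:3) {
          y[c0, a, d, gi, gj] <- if (qc[gi, gj] > 0)
            sum(w * Xg[, a, d]) / qc[gi, gj] else mean(Xg[, a, d])
        }
      }
    }
  }
  chi1 <- vapply(seq_len(nc), function(c0) {
    u <- unique(tp$chi1_bin[mapping == c0])
    if (length(u) > 1) NA_integer_ else as.integer(u)
  }, integer(1))
  list(mapping = as.integer(mapping), n_coarse = nc, q = q, y = y,
       chi1_of_state = chi1, zero_q = zero_q)
}

#' Ramachandran-weighted coarse-graining error of a partition
#'
#' The per-grid-point error is the probability-weighted squared deviation of
#' the fine-state atom positions from their coarse-state means, divided by
#' the number of atoms; it is then integrated against the Ramachandran
#' density by the midpoint rule.
#'
#' @inheritParams coarse_states
#' @param rama a [rama_density()] on the same grid.
#' @return scalar error in Angstrom^2, with attribute `"grid"` holding the
#'   per-grid-point error surface.
#' @export
partition_error <- function(library, mapping, rama,
                            type = names(library$types)[1]) {
  tp <- library$types[[type]]
  cs <- coarse_states(library, mapping, type)
  G <- length(library$centers)
  na <- dim(tp$atoms)[2]
  nf <- length(tp$chi1_bin)
  const_atoms <- length(dim(tp$atoms)) == 3L
  sig <- matrix(0, G, G)
  for (f in seq_len(nf)) {
    c0 <- cs$mapping[f]
    dev <- matrix(0, G, G)
    for (a in seq_len(na)) for (d in 1:3) {
      xf <- if (const_atoms) tp$atoms[f, a, d] else tp$atoms[f, a, d, , ]
      dev <- dev + (xf - cs$y[c0, a, d, , ])^2
    }
    sig <- sig + tp$prob[f, , ] * dev / na
  }
  out <- sum(rama$density * sig) * rama$delta^2
  attr(out, "grid") <- sig
  out
}

# All partitions of m circularly-ordered chi2 bins into contiguous arcs.
# Returns a list of candidate partitions, each an integer vector of arc ids
# (1-based, arcs numbered by their smallest member).
.circular_arc_partitions <- function(m) {
  out <- list(rep(1L, m))
  if (m == 1) return(out)
  for (k in 2:m) {
    cuts <- utils::combn(m, k)
    for (ci in seq_len(ncol(cuts))) {
      cut <- cuts[, ci]     # arc starts
      lab <- integer(m)
      for (ai in seq_len(k)) {
        from <- cut[ai]
        to <- if (ai < k) cut[ai + 1] - 1L else cut[1] - 1L + m
        idx <- ((from:to - 1L) %% m) + 1L
        lab[idx] <- ai
      }
      # renumber arcs in first-appearance order for a canonical label
      lab <- match(lab, unique(lab))
      out[[length(out) + 1L]] <- lab
    }
  }
  out
}

# Expand a per-(chi1, chi2) block labelling into a fine-state mapping.
.mapping_from_blocks <- function(tp, block_of_chi2) {
  # block_of_chi2: list per chi1 bin of integer arc labels per chi2 bin
  nf <- length(tp$chi1_bin)
  key <- integer(nf)
  next_id <- 0L
  ids <- list()
  for (f in seq_len(nf)) {
    b <- block_of_chi2[[tp$chi1_bin[f]]][tp$chi2_bin[f]]
    k <- paste(tp$chi1_bin[f], b)
    if (is.null(ids[[k]])) { next_id <- next_id + 1L; ids[[k]] <- next_id }
    key[f] <- ids[[k]]
  }
  key
}

#' Optimal admissible coarse partition of a rotamer library
#'
#' Enumerates every partition of the fine states that (1) depends only on
#' the chi1/chi2 bins, (2) keeps each coarse state within a single chi1 bin,
#' and (3) pools only circularly contiguous chi2 bins, and returns the one
#' minimizing the Ramachandran-weighted positional variance with at most
#' `max_states` coarse states per residue type.  Ties break to the
#' lexicographically smallest mapping.
#'
#' @param library a [fine_rotamer_library()].
#' @param rama a [rama_density()].
#' @param max_states maximum number of coarse states per residue type.
#' @return object of class `coarse_partition`: per type the optimal
#'   `mapping`, `n_coarse`, `sigma2`, `q`, `y`, `chi1_of_state`.
#' @export
optimize_partition <- function(library, rama, max_states = 6L) {
  res <- list()
  for (nm in names(library$types)) {
    tp <- library$types[[nm]]
    n1 <- tp$n_chi1
    n2 <- tp$n_chi2
    if (n1 > max_states)
      stop("infeasible: ", nm, " has ", n1, " chi1 bins but max_states = ",
           max_states)
    arcs <- .circular_arc_partitions(n2)
    sizes <- vapply(arcs, max, integer(1))
    # enumerate the product of per-chi1 arc partitions under the state budget
    best <- NULL
    combo <- vector("list", n1)
    recurse <- function(lvl, used) {
      if (lvl > n1) {
        mp <- .mapping_from_blocks(tp, combo)
        s2 <- as.numeric(partition_error(library, mp, rama, nm))
        if (is.null(best) || s2 < best$sigma2 - 1e-15 ||
            (abs(s2 - best$sigma2) <= 1e-15 &&
             .lex_less(mp, best$mapping))) {
          best <<- list(mapping = mp, sigma2 = s2)
        }
        return(invisible())
      }
      for (ai in seq_along(arcs)) {
        if (used + sizes[ai] + (n1 - lvl) > max_states) next
        combo[[lvl]] <<- arcs[[ai]]
        recurse(lvl + 1L, used + sizes[ai])
      }
      invisible()
    }
    recurse(1L, 0L)
    if (is.null(best)) stop("no admissible partition for ", nm)
    cs <- coarse_states(library, best$mapping, nm)
    res[[nm]] <- c(cs, list(sigma2 = best$sigma2))
  }
  structure(list(types = res, centers = library$centers),
            class = "coarse_partition")
}

.lex_less <- function(a, b) {
  d <- a - b
  k <- which(d != 0)
  length(k) > 0 && d[k[1]] < 0
}

#' Check the structural constraints of a coarse partition
#'
#' @param library a [fine_rotamer_library()].
#' @param mapping integer mapping `c(f)`.
#' @param type residue type name.
#' @return TRUE invisibly, or an error describing the violated constraint.
#' @export
check_partition_constraints <- function(library, mapping,
                                        type = names(library$types)[1]) {
  tp <- library$types[[type]]
  nf <- length(tp$chi1_bin)
  stopifnot(length(mapping) == nf)
  # constraint 1: depends only on (chi1, chi2)
  key <- paste(tp$chi1_bin, tp$chi2_bin)
  for (k in unique(key))
    if (length(unique(mapping[key == k])) > 1)
      stop("partition differs within a (chi1, chi2) bin")
  for (c0 in unique(mapping)) {
    sel <- mapping == c0
    if (length(unique(tp$chi1_bin[sel])) > 1)
      stop("coarse state spans multiple chi1 bins")
    bins <- sort(unique(tp$chi2_bin[sel]))
    if (!.circularly_contiguous(bins, tp$n_chi2))
      stop("coarse state pools non-contiguous chi2 bins")
  }
  invisible(TRUE)
}

.circularly_contiguous <- function(bins, m) {
  if (length(bins) >= m || length(bins) <= 1) return(TRUE)
  present <- seq_len(m) %in% bins
  # number of FALSE->TRUE transitions around the circle must be 1
  trans <- sum(present != c(present[-1], present[1]))
  trans <= 2
}

#' Derive oriented-bead reference placements from a coarse partition
#'
#' The bead position of a coarse state is the Ramachandran-weighted mean of
#' its atom centroid; the direction is the unit vector from the first to the
#' second atom (a CB-to-CG style bond vector), or the radial direction of
#' the centroid for single-atom side chains.
#'
#' @param partition a [coarse_states()] result or `coarse_partition` entry.
#' @param rama a [rama_density()].
#' @return list with `bead_pos` and `bead_dir` (n_states x 3 matrices).
#' @export
beads_from_partition <- function(partition, rama) {
  nc <- partition$n_coarse
  na <- dim(partition$y)[2]
  w <- rama$density * rama$delta^2
  pos <- matrix(0, nc, 3)
  dir <- matrix(0, nc, 3)
  for (c0 in seq_len(nc)) {
    qw <- partition$q[c0, , ] * w
    z <- sum(qw)
    if (z <= 0) { qw <- w; z <- sum(qw) }
    for (d in 1:3) {
      cen <- apply(partition$y[c0, , d, , , drop = FALSE], c(4, 5), mean)
      pos[c0, d] <- sum(qw * cen) / z
      if (na >= 2) {
        bd <- partition$y[c0, 2, d, , ] - partition$y[c0, 1, d, , ]
        dir[c0, d] <- sum(qw * bd) / z
      }
    }
    if (na < 2) dir[c0, ] <- pos[c0, ]
    n <- sqrt(sum(dir[c0, ]^2))
    dir[c0, ] <- if (n > 0) dir[c0, ] / n else c(1, 0, 0)
  }
  list(bead_pos = pos, bead_dir = dir)
}
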