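# The trainable parameter set: per residue-type bead reference placements,
# 1-body rotamer energy tables, and spline blocks for every interaction
# class (side chain-side chain, side chain-O, side chain-H, side
# chain-N/CA/C three-bead).  Pair blocks are stored once per unordered type
# pair; the first slot of the directional term belongs to the
# alphabetically first type.

default_model_config <- function() {
  list(cutoff_scsc = 7, cutoff_scbb = 5,
       sc_sc = TRUE, sc_bb = TRUE,
       use_HO = TRUE, use_NCAC = TRUE,
       ncac_directional = FALSE,
       include_intra_backbone = FALSE,
       phi_psi_independent = FALSE,
       repulsive_only = FALSE,
       min_seq_sep = 1L,
       hbond_energy = -1.8)
}

sc_pair_key <- function(a, b) paste0("sc|", min(a, b), "|", max(a, b))
bb_pair_key <- function(type, site) paste0("bb|", type, "|", site)

#' Assemble a parameter set from a coarse partition
#'
#' Builds bead reference placements and 1-body rotamer priors from an
#' optimized coarse partition, and default spline blocks for every
#' interaction pair.  The rotamer prior is `-log q^c(phi, psi)`; a
#' phi/psi-independent variant (Ramachandran-averaged) is stored alongside
#' for terminal residues and for the corresponding ablation.
#'
#' @param partition a `coarse_partition` from [optimize_partition()].
#' @param rama the [rama_density()] used for averaging.
#' @param config model flags; see `default_model_config`.
#' @param geometry internal-coordinate constants.
#' @return object of class `parameter_set`.
#' @export
make_parameter_set <- function(partition, rama,
                               config = default_model_config(),
                               geometry = default_geometry_params()) {
  types <- list()
  w <- rama$density * rama$delta^2
  for (nm in names(partition$types)) {
    pt <- partition$types[[nm]]
    bd <- beads_from_partition(pt, rama)
    prior <- -log(pmax(pt$q, 1e-8))
    qbar <- apply(pt$q, 1, function(qc) sum(matrix(qc, dim(pt$q)[2]) * w))
    types[[nm]] <- list(n_states = pt$n_coarse,
                        bead_pos = bd$bead_pos, bead_dir = bd$bead_dir,
                        chi1_of_state = pt$chi1_of_state,
                        rot_prior = prior,
                        prior_indep = -log(pmax(qbar, 1e-8)))
  }
  tn <- names(types)
  pair <- list()
  for (a in tn) for (b in tn) if (a <= b)
    pair[[sc_pair_key(a, b)]] <- default_pair_params(config$cutoff_scsc, TRUE)
  for (a in tn) {
    pair[[bb_pair_key(a, "O")]] <- default_pair_params(config$cutoff_scbb, TRUE)
    pair[[bb_pair_key(a, "H")]] <- default_pair_params(config$cutoff_scbb, TRUE)
    pair[[bb_pair_key(a, "NCAC")]] <-
      default_pair_params(config$cutoff_scbb, isTRUE(config$ncac_directional))
  }
  structure(list(types = types, pair = pair,
                 backbone_beads = geometry$reference_ncac,
                 geometry = geometry, config = config,
                 grid_centers = partition$centers,
                 hbond = default_hbond_criteria(),
                 backbone = default_backbone_springs(),
                 version = "scpack-params-1"),
            class = "parameter_set")
}

#' Ablation presets for the interaction model
#'
#' Returns a modified copy of a parameter set implementing one of the
#' functional-form restrictions used to probe which energy terms matter:
#' dropping hydrogen/oxygen or N/CA/C backbone sites, isotropic-only or
#' repulsive-only splines, a phi/psi-independent rotamer prior, restricting
#' to side chain-side chain or side chain-backbone terms only, longer
#' cutoffs, or no interactions at all.
#'
#' @param params a `parameter_set`.
#' @param name one of `"full"`, `"cutoff10"`, `"no_HO"`, `"no_NCAC"`,
#'   `"phi_psi_independent"`, `"isotropic_only"`, `"repulsive_only"`,
#'   `"sc_sc_only"`, `"sc_bb_only"`, `"no_interactions"`.
#' @return modified `parameter_set`.
#' @export
ablation_preset <- function(params, name = "full") {
  p <- params
  switch(name,
    full = p,
    cutoff10 = {
      p$config$cutoff_scsc <- 10; p$config$cutoff_scbb <- 10
      for (k in names(p$pair)) {
        dirc <- p$pair[[k]]$directional
        p$pair[[k]] <- default_pair_params(10, dirc)
      }
      p
    },
    no_HO = { p$config$use_HO <- FALSE; p },
    no_NCAC = { p$config$use_NCAC <- FALSE; p },
    phi_psi_independent = { p$config$phi_psi_independent <- TRUE; p },
    isotropic_only = {
      for (k in names(p$pair)) p$pair[[k]]$directional <- FALSE
      p
    },
    repulsive_only = {
      for (k in names(p$pair)) {
        p$pair[[k]]$directional <- FALSE
        p$pair[[k]]$radial <- pmax(p$pair[[k]]$radial, 0)
      }
      p$config$repulsive_only <- TRUE
      p
    },
    sc_sc_only = { p$config$sc_bb <- FALSE; p },
    sc_bb_only = { p$config$sc_sc <- FALSE; p },
    no_interactions = { p$config$sc_sc <- FALSE; p$config$sc_bb <- FALSE; p },
    stop("unknown preset: ", name)
  )
}

# ---- flattening of trainable spline coefficients ------------------------

# The trainable vector holds, per pair block, the radial knot values except
# the structurally zero last knot, the directional envelope likewise, and
# the log-coefficients of both angular factors.  Blocks whose pair is
# isotropic contribute only their radial part.
param_layout <- function(params, keys = NULL) {
  if (is.null(keys)) keys <- names(params$pair)
  lay <- list(); off <- 0L
  for (k in keys) {
    pp <- params$pair[[k]]
    K <- length(pp$radial)
    ent <- list(key = k, radial = off + seq_len(K - 1L))
    off <- off + K - 1L
    if (isTRUE(pp$directional)) {
      ent$angular <- off + seq_len(K - 1L); off <- off + K - 1L
      ent$ang1 <- off + seq_len(ANGULAR_KNOTS); off <- off + ANGULAR_KNOTS
      ent$ang2 <- off + seq_len(ANGULAR_KNOTS); off <- off + ANGULAR_KNOTS
    }
    lay[[k]] <- ent
  }
  attr(lay, "n") <- off
  lay
}

#' Flatten trainable spline coefficients into a parameter vector
#' @param params a `parameter_set`.
#' @param keys pair-block keys to include (default: all).
#' @return numeric vector with attribute `"layout"`.
#' @export
flatten_params <- function(params, keys = NULL) {
  lay <- param_layout(params, keys)
  th <- numeric(attr(lay, "n"))
  for (ent in lay) {
    pp <- params$pair[[ent$key]]
    K <- length(pp$radial)
    th[ent$radial] <- pp$radial[-K]
    if (!is.null(ent$angular)) {
      th[ent$angular] <- pp$angular[-K]
      th[ent$ang1] <- pp$ang1
      th[ent$ang2] <- pp$ang2
    }
  }
  attr(th, "layout") <- lay
  th
}

#' Write a trainable parameter vector back into a parameter set
#' @param params a `parameter_set`.
#' @param theta vector from [flatten_params()] (same layout).
#' @param layout optional explicit layout.
#' @return updated `parameter_set`.
#' @export
unflatten_params <- function(params, theta, layout = attr(theta, "layout")) {
  if (is.null(layout)) layout <- param_layout(params)
  for (ent in layout) {
    pp <- params$pair[[ent$key]]
    K <- length(pp$radial)
    pp$radial[-K] <- theta[ent$radial]
    pp$radial[K] <- 0
    if (!is.null(ent$angular)) {
      pp$angular[-K] <- theta[ent$angular]
      pp$angular[K] <- 0
      pp$ang1 <- theta[ent$ang1]
      pp$ang2 <- theta[ent$ang2]
    }
    params$pair[[ent$key]] <- pp
  }
  params
}
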