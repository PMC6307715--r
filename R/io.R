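# Readers and writers.  PDB backbones are parsed with bio3d; the rotamer
# library, Ramachandran table and parameter set use a versioned JSON
# schema (arrays stored flat with explicit dimensions, full 17-digit
# precision so that round trips are bit-exact).

.pack_array <- function(a) list(dim = dim(a), data = as.numeric(a))
.unpack_array <- function(x) array(as.numeric(x$data), dim = as.integer(x$dim))
.pack_matrix <- function(m) list(dim = dim(m), data = as.numeric(m))
.unpack_matrix <- function(x) matrix(as.numeric(x$data), as.integer(x$dim[1]),
                                     as.integer(x$dim[2]))

.write_json <- function(obj, path) {
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(unname(tools::md5sum(path)))
}

.read_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Read an N/CA/C backbone from a PDB file
#'
#' First model, first alternate location; residues missing any of N, CA or
#' C are skipped with a warning (error in strict mode).
#'
#' @param path PDB file.
#' @param chain chain identifier (default: first chain in the file).
#' @param strict error instead of skipping incomplete residues.
#' @return a [backbone_chain()].
#' @export
read_backbone_pdb <- function(path, chain = NULL, strict = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C"), ]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, ]
  if (!nrow(at)) stop("no backbone atoms found in ", path)
  key <- paste(at$resno, at$insert)
  res_keys <- unique(key)
  N <- CA <- C <- NULL
  types <- character(0)
  for (k in res_keys) {
    sub <- at[key == k, ]
    pick <- function(nm) {
      row <- sub[sub$elety == nm, , drop = FALSE]
      if (!nrow(row)) return(NULL)
      as.numeric(row[1, c("x", "y", "z")])
    }
    n <- pick("N"); ca <- pick("CA"); cc <- pick("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      msg <- paste0("residue ", k, " missing a backbone atom")
      if (strict) stop(msg) else { warning(msg, "; skipped"); next }
    }
    N <- rbind(N, n); CA <- rbind(CA, ca); C <- rbind(C, cc)
    types <- c(types, sub$resid[1])
  }
  if (is.null(N)) stop("no complete residues in ", path)
  backbone_chain(types, N, CA, C, chain_id = chain)
}

.pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                           element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

#' Write a backbone chain as a PDB file
#'
#' @param chain a [backbone_chain()].
#' @param path output file.
#' @param derived optional O/H atoms from [place_peptide_atoms()] to
#'   include.
#' @return the path, invisibly.
#' @export
write_backbone_pdb <- function(chain, path, derived = NULL) {
  lines <- .chain_pdb_lines(chain, derived)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.chain_pdb_lines <- function(chain, derived = NULL) {
  n <- length(chain$residues)
  lines <- character(0); serial <- 0L
  for (i in seq_len(n)) {
    emit <- function(name, xyz, elem) {
      serial <<- serial + 1L
      lines <<- c(lines, .pdb_atom_line(serial, name, chain$residues[i],
                                        chain$chain_id, i, xyz, elem))
    }
    emit("N", chain$N[i, ], "N")
    emit("CA", chain$CA[i, ], "C")
    emit("C", chain$C[i, ], "C")
    if (!is.null(derived)) {
      if (all(is.finite(derived$O[i, ]))) emit("O", derived$O[i, ], "O")
      if (all(is.finite(derived$H[i, ]))) emit("H", derived$H[i, ], "H")
    }
  }
  lines
}

#' Write a trajectory as a multi-model PDB plus a TSV energy log
#'
#' @param traj a `trajectory` from [run_simulation()].
#' @param path output PDB path.
#' @param replica replica index to export.
#' @param energy_path optional TSV path for the energy log.
#' @return the PDB path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, replica = 1L,
                                 energy_path = NULL) {
  lines <- character(0)
  for (k in seq_along(traj$frames[[replica]])) {
    ch <- chain_from_coords(traj$chain, traj$frames[[replica]][[k]])
    lines <- c(lines, sprintf("MODEL %8d", k),
               .chain_pdb_lines(ch), "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  if (!is.null(energy_path))
    utils::write.table(traj$energies, energy_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a fine rotamer library (versioned JSON)
#'
#' Probabilities are validated on load: a per-grid-point normalization off
#' by more than 1e-6 is rejected.
#'
#' @param library a [fine_rotamer_library()].
#' @param path file path.
#' @return `write_rotamer_library` returns the file's md5 checksum
#'   invisibly; `read_rotamer_library` returns the library.
#' @export
write_rotamer_library <- function(library, path) {
  obj <- list(schema = "scpack-rotlib-1",
              centers = library$centers,
              types = lapply(library$types, function(tp) list(
                chi1_bin = tp$chi1_bin, chi2_bin = tp$chi2_bin,
                chi_higher = tp$chi_higher,
                n_chi1 = tp$n_chi1, n_chi2 = tp$n_chi2,
                prob = .pack_array(tp$prob),
                atoms = .pack_array(tp$atoms))))
  invisible(.write_json(obj, path))
}

#' @rdname write_rotamer_library
#' @export
read_rotamer_library <- function(path) {
  obj <- .read_json(path)
  if (!identical(obj$schema, "scpack-rotlib-1"))
    stop("unsupported rotamer library schema: ", obj$schema)
  types <- lapply(obj$types, function(tp) list(
    chi1_bin = as.integer(tp$chi1_bin), chi2_bin = as.integer(tp$chi2_bin),
    chi_higher = as.integer(tp$chi_higher),
    n_chi1 = as.integer(tp$n_chi1), n_chi2 = as.integer(tp$n_chi2),
    prob = .unpack_array(tp$prob), atoms = .unpack_array(tp$atoms)))
  lib <- fine_rotamer_library(types, as.numeric(obj$centers))
  for (nm in names(lib$types)) {
    s <- apply(lib$types[[nm]]$prob, c(2, 3), sum)
    if (max(abs(s - 1)) > 1e-6)
      stop("probabilities not normalized in ", nm)
  }
  lib
}

#' Write / read a Ramachandran density (JSON)
#' @param rama a [rama_density()].
#' @param path file path.
#' @export
write_rama_density <- function(rama, path) {
  invisible(.write_json(list(schema = "scpack-rama-1",
                             centers = rama$centers,
                             density = .pack_matrix(rama$density)), path))
}

#' @rdname write_rama_density
#' @export
read_rama_density <- function(path) {
  obj <- .read_json(path)
  if (!identical(obj$schema, "scpack-rama-1"))
    stop("unsupported Ramachandran schema: ", obj$schema)
  rama_density(.unpack_matrix(obj$density), as.numeric(obj$centers))
}

#' Write / read a parameter set (versioned JSON, bit-exact round trip)
#' @param params a `parameter_set`.
#' @param path file path.
#' @export
write_parameters <- function(params, path) {
  obj <- list(schema = "scpack-params-1",
              grid_centers = params$grid_centers,
              geometry = list(O_bond = params$geometry$O_bond,
                              H_bond = params$geometry$H_bond,
                              virtN_bond = params$geometry$virtN_bond,
                              virtN_angle = params$geometry$virtN_angle,
                              virtN_torsion = params$geometry$virtN_torsion,
                              reference_ncac = .pack_matrix(params$geometry$reference_ncac)),
              config = params$config,
              hbond = params$hbond,
              backbone = params$backbone,
              backbone_beads = .pack_matrix(params$backbone_beads),
              types = lapply(params$types, function(tp) list(
                n_states = tp$n_states,
                bead_pos = .pack_matrix(tp$bead_pos),
                bead_dir = .pack_matrix(tp$bead_dir),
                chi1_of_state = tp$chi1_of_state,
                rot_prior = .pack_array(tp$rot_prior),
                prior_indep = tp$prior_indep)),
              pair = lapply(params$pair, function(pp) list(
                radial = pp$radial, angular = pp$angular,
                ang1 = pp$ang1, ang2 = pp$ang2,
                cutoff = pp$cutoff, directional = pp$directional)))
  invisible(.write_json(obj, path))
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- .read_json(path)
  if (!identical(obj$schema, "scpack-params-1"))
    stop("unsupported parameter schema: ", obj$schema)
  geometry <- list(O_bond = obj$geometry$O_bond, H_bond = obj$geometry$H_bond,
                   virtN_bond = obj$geometry$virtN_bond,
                   virtN_angle = obj$geometry$virtN_angle,
                   virtN_torsion = obj$geometry$virtN_torsion,
                   reference_ncac = .unpack_matrix(obj$geometry$reference_ncac))
  types <- lapply(obj$types, function(tp) list(
    n_states = as.integer(tp$n_states),
    bead_pos = .unpack_matrix(tp$bead_pos),
    bead_dir = .unpack_matrix(tp$bead_dir),
    chi1_of_state = as.integer(tp$chi1_of_state),
    rot_prior = .unpack_array(tp$rot_prior),
    prior_indep = as.numeric(tp$prior_indep)))
  pair <- lapply(obj$pair, function(pp) list(
    radial = as.numeric(pp$radial), angular = as.numeric(pp$angular),
    ang1 = as.numeric(pp$ang1), ang2 = as.numeric(pp$ang2),
    cutoff = as.numeric(pp$cutoff), directional = isTRUE(pp$directional)))
  cfg <- obj$config
  cfg$min_seq_sep <- as.integer(cfg$min_seq_sep)
  structure(list(types = types, pair = pair,
                 backbone_beads = .unpack_matrix(obj$backbone_beads),
                 geometry = geometry, config = cfg,
                 grid_centers = as.numeric(obj$grid_centers),
                 hbond = obj$hbond, backbone = obj$backbone,
                 version = obj$schema),
            class = "parameter_set")
}
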