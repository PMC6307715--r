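# Residue-pair neighbor graph.  Two residues interact if their side-chain
# beads come within the cutoff for ANY pair of coarse states, so the edge
# set is a function of the full state-resolved bead cloud.  A cell-list
# accelerator reproduces the brute-force edge set exactly; because the pair
# potential vanishes at the cutoff, the energy is continuous across edge
# creation/deletion events.

#' Build the side-chain interaction graph
#'
#' @param beads list per residue of `n_states x 3` bead position matrices.
#' @param sites optional data frame of backbone interaction sites with
#'   columns `residue` (owner index) and `x`, `y`, `z`; used for side
#'   chain-backbone neighbor pairs.
#' @param cutoff_scsc side chain-side chain cutoff (Angstrom, default 7).
#' @param cutoff_scbb side chain-backbone cutoff (Angstrom, default 5).
#' @param min_seq_sep minimum |i - j| for an edge (default 1: sequence
#'   neighbors are allowed).
#' @param include_self if TRUE a residue may pair with its own backbone
#'   sites (default FALSE: only other residues' sites contribute).
#' @param method `"brute"`, `"cells"`, or `"auto"` (cells above 150
#'   residues).
#' @return list with `edges` (2-column matrix, i < j) and `scbb` (data
#'   frame `residue`, `site` of in-range side chain-backbone pairs).
#' @export
build_graph <- function(beads, sites = NULL, cutoff_scsc = 7,
                        cutoff_scbb = 5, min_seq_sep = 1L,
                        method = c("auto", "brute", "cells"),
                        include_self = FALSE) {
  method <- match.arg(method)
  n <- length(beads)
  if (method == "auto") method <- if (n > 150) "cells" else "brute"
  P <- do.call(rbind, beads)
  owner <- rep(seq_len(n), vapply(beads, nrow, integer(1)))
  edges <- if (method == "brute")
    .graph_brute(P, owner, n, cutoff_scsc, min_seq_sep)
  else
    .graph_cells(P, owner, n, cutoff_scsc, min_seq_sep)
  scbb <- NULL
  if (!is.null(sites) && nrow(sites) > 0) {
    S <- as.matrix(sites[, c("x", "y", "z")])
    hits <- list()
    for (s in seq_len(nrow(sites))) {
      d2 <- rowSums(sweep(P, 2, S[s, ])^2)
      res <- sort(unique(owner[d2 < cutoff_scbb^2]))
      if (!include_self) res <- res[res != sites$residue[s]]
      if (length(res))
        hits[[length(hits) + 1L]] <- data.frame(residue = res, site = s)
    }
    scbb <- if (length(hits)) do.call(rbind, hits) else
      data.frame(residue = integer(), site = integer())
  }
  list(edges = edges, scbb = scbb)
}

.graph_brute <- function(P, owner, n, cutoff, min_seq_sep) {
  D2 <- as.matrix(stats::dist(P))^2
  out <- NULL
  for (i in seq_len(n - 1)) {
    ri <- which(owner == i)
    for (j in (i + 1):n) {
      if (j - i < min_seq_sep) next
      rj <- which(owner == j)
      if (min(D2[ri, rj]) < cutoff^2) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

.graph_cells <- function(P, owner, n, cutoff, min_seq_sep) {
  cell <- floor(sweep(P, 2, apply(P, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(nrow(P)), key)
  coords <- unique(cell)
  lookup <- new.env(parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  cand <- new.env(parent = emptyenv())
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in names(buckets)) {
    ijk <- as.integer(strsplit(b, " ")[[1]])
    here <- buckets[[b]]
    for (o in seq_len(nrow(offs))) {
      nb <- paste(ijk[1] + offs[o, 1], ijk[2] + offs[o, 2], ijk[3] + offs[o, 3])
      there <- if (exists(nb, envir = lookup, inherits = FALSE))
        get(nb, envir = lookup) else NULL
      if (is.null(there)) next
      for (a in here) {
        close <- there[colSums((t(P[there, , drop = FALSE]) - P[a, ])^2) < cutoff^2]
        for (bb in close) {
          ri <- owner[a]; rj <- owner[bb]
          if (ri == rj || abs(ri - rj) < min_seq_sep) next
          kk <- paste(min(ri, rj), max(ri, rj))
          assign(kk, TRUE, envir = cand)
        }
      }
    }
  }
  ks <- ls(cand)
  if (!length(ks)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, lapply(strsplit(ks, " "), as.integer))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  m
}
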