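## CA coordinates, CA-CA distance matrices and contact maps on the
## distance-cutoff ladder.

#' The distance-cutoff ladder (angstroms)
#'
#' The thirteen cutoffs at which contact maps are evaluated: 3.8, 4.0,
#' 4.5, 5.0, 5.5, 6.0 and then every 2 A from 8 to 20.  The short end
#' brackets the consecutive-CA spacing (~3.8 A); the long end extends
#' well past any direct physical contact so the characteristic distance
#' of every predictor falls inside the ladder.
#'
#' @return numeric vector of cutoffs, strictly increasing
#' @export
contactLadderCutoffs <- function() {
  c(3.8, 4.0, 4.5, 5.0, 5.5, 6.0, 8.0, 10.0, 12.0, 14.0, 16.0, 18.0, 20.0)
}

#' Read CA coordinates for one chain of a PDB file
#'
#' Parses the file with \code{bio3d::read.pdb} and keeps one CA atom per
#' residue of the requested chain.  Alternate locations are resolved to
#' the highest occupancy (ties: first in file); residues lacking a CA are
#' skipped with a warning.  Residue identity follows author numbering
#' (resno + insertion code order as in the file).
#'
#' @param path PDB-format file
#' @param chain chain identifier (single character)
#' @return data.frame with columns resno, x, y, z (one row per residue,
#'   file order) and attribute \code{"resid"} holding the 3-letter residue
#'   names
#' @export
readCaCoordinates <- function(path, chain) {
  if (!file.exists(path))
    stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains)
    stop("chain '", chain, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no CA atoms found in chain '", chain, "'")
  ins <- ca$insert
  ins[is.na(ins)] <- ""
  key <- paste(ca$resno, ins)
  # altloc: keep highest occupancy within each residue, ties -> first in file
  occ <- ca$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(idx) idx[which.max(occ[idx])]),
                 use.names = FALSE)
  keep <- sort(keep)
  ca <- ca[keep, , drop = FALSE]
  nres <- length(unique(paste(at$resno, ifelse(is.na(at$insert), "",
                                               at$insert))))
  if (nrow(ca) < nres)
    warning(nres - nrow(ca), " residue(s) lacking a CA atom were skipped")
  out <- data.frame(resno = ca$resno, x = ca$x, y = ca$y, z = ca$z)
  attr(out, "resid") <- ca$resid
  out
}

#' CA-CA Euclidean distance matrix
#'
#' @param coords data.frame with x, y, z columns (one row per residue)
#' @return symmetric n x n matrix of distances in angstroms, zero diagonal
#' @export
distanceMatrix <- function(coords) {
  if (nrow(coords) < 2L)
    stop("need >= 2 residues")
  d <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  dimnames(d) <- NULL
  d
}

#' Contact map at one distance cutoff
#'
#' All unordered residue pairs (i < j) with d(i,j) <= cutoff.  The pair
#' universe is every unordered pair, n(n-1)/2 — no minimum sequence
#' separation, so chain neighbours (always within ~3.8 A) are contacts at
#' every ladder cutoff.
#'
#' @param dm distance matrix from [distanceMatrix()]
#' @param cutoff distance cutoff in angstroms (> 0); the boundary is
#'   closed (d equal to the cutoff is a contact)
#' @return a [ContactMap-class] object
#' @export
contactMap <- function(dm, cutoff) {
  if (cutoff <= 0)
    stop("cutoff must be positive")
  n <- nrow(dm)
  idx <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  contacts <- matrix(as.integer(idx), ncol = 2L)
  # order rows by (i, j) for reproducible output
  o <- order(contacts[, 1L], contacts[, 2L])
  new("ContactMap", cutoff = cutoff,
      contacts = contacts[o, , drop = FALSE], n = as.integer(n))
}

#' Contact maps across a cutoff ladder
#'
#' @param dm distance matrix
#' @param cutoffs increasing vector of cutoffs
#'   (default [contactLadderCutoffs()])
#' @return named list of [ContactMap-class] objects; maps are nested:
#'   contacts at a smaller cutoff are a subset of those at any larger one
#' @export
contactMapLadder <- function(dm, cutoffs = contactLadderCutoffs()) {
  stats::setNames(lapply(cutoffs, function(ct) contactMap(dm, ct)),
                  sprintf("%.1f", cutoffs))
}

#' Write pairwise distances and per-cutoff contact flags as TSV
#'
#' @param dm distance matrix
#' @param path output file
#' @param cutoffs cutoffs for the boolean contact columns
#' @return invisibly, the path
#' @export
writeContactTable <- function(dm, path, cutoffs = contactLadderCutoffs()) {
  n <- nrow(dm)
  ij <- which(upper.tri(dm), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  d <- dm[ij]
  tab <- data.frame(i = ij[, 1L], j = ij[, 2L], dist = round(d, 3))
  for (ct in cutoffs)
    tab[[sprintf("c%.1f", ct)]] <- as.integer(d <= ct)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
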