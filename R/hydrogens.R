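# Amide hydrogen reconstruction. The Kabsch-Sander energy needs the
# backbone H; input structures (and PDB files stripped of hydrogens) often
# lack it. H is placed 0.10 nm from N along the normalized sum of the unit
# vectors N->C(prev) and N->O(prev), both reversed - the bisector of the
# two repulsive directions.

# Per-residue amide H positions for one frame without touching the
# topology: existing H atoms pass through, missing ones are computed.
# Returns an nResidues x 3 matrix with NA rows where no H is defined
# (caps, ligands, first residue without cap context).
amideHydrogenPositions <- function(topology, coords, warn = TRUE) {
  n <- length(topology@residues)
  out <- matrix(NA_real_, n, 3)
  at <- topology@atoms
  for (ri in seq_len(n)) {
    r <- topology@residues[[ri]]
    if (isCapName(r$name)) next
    kind <- topology@chains$kind[match(r$chainId, topology@chains$id)]
    if (kind != "peptide") next
    nmv <- at$name[r$atoms]
    hAt <- r$atoms[nmv == "H"]
    if (length(hAt)) { out[ri, ] <- coords[hAt[1], ]; next }
    nAt <- r$atoms[nmv == "N"]
    if (!length(nAt)) next
    prev <- prevResidueInChain(topology, ri)
    if (is.na(prev)) {
      if (warn)
        warning(sprintf("residue %s%d: no preceding carbonyl; amide H skipped",
                        r$name, r$seqNumber), call. = FALSE)
      next
    }
    pr <- topology@residues[[prev]]
    pn <- at$name[pr$atoms]
    cAt <- pr$atoms[pn == "C"]; oAt <- pr$atoms[pn == "O"]
    if (!length(cAt) || !length(oAt)) next
    out[ri, ] <- amideHydrogenFromContext(coords[nAt[1], ], coords[cAt[1], ],
                                          coords[oAt[1], ])
  }
  out
}

prevResidueInChain <- function(topology, ri) {
  r <- topology@residues[[ri]]
  if (ri == 1L) return(NA_integer_)
  p <- topology@residues[[ri - 1L]]
  if (p$chainId == r$chainId) ri - 1L else NA_integer_
}

#' Reconstruct missing backbone amide hydrogens
#'
#' For every peptide amide nitrogen lacking an explicit H atom, a hydrogen
#' is placed 0.10 nm from N along the normalized sum of the normalized
#' N-C(prev) and N-O(prev) directions. Residues already carrying an amide
#' H are left unchanged; a first residue without an acetyl cap is skipped
#' with a warning. New atoms are appended at the end of the atom table so
#' existing atom indices remain valid.
#'
#' @param traj a [Trajectory-class].
#' @return a [Trajectory-class] whose topology includes an amide H for
#'   every reconstructable residue.
#' @export
reconstructAmideHydrogens <- function(traj) {
  top <- traj@topology
  at <- top@atoms
  nOld <- nrow(at)
  hpos <- lapply(seq_len(nFrames(traj)), function(f)
    amideHydrogenPositions(top, traj@coords[[f]], warn = (f == 1L)))
  needs <- which(vapply(seq_along(top@residues), function(ri) {
    r <- top@residues[[ri]]
    all(is.finite(hpos[[1]][ri, ])) && !any(at$name[r$atoms] == "H")
  }, TRUE))
  if (!length(needs)) return(traj)
  newRows <- data.frame(serial = nOld + seq_along(needs),
                        name = "H", element = "H",
                        resIndex = needs, isHydrogen = TRUE,
                        mass = elementMass("H"), vdw = NA_real_,
                        stringsAsFactors = FALSE)
  at2 <- rbind(at, newRows)
  res2 <- top@residues
  for (k in seq_along(needs)) {
    ri <- needs[k]
    idx <- nOld + k
    res2[[ri]]$atoms <- c(res2[[ri]]$atoms, idx)
    d <- res2[[ri]]$donors
    if (!is.null(d)) {
      nAt <- res2[[ri]]$atoms[at2$name[res2[[ri]]$atoms] == "N"][1]
      miss <- which(d[, 1] == nAt & is.na(d[, 2]))
      if (length(miss)) d[miss[1], 2] <- idx else d <- rbind(d, c(nAt, idx))
      res2[[ri]]$donors <- d
    }
  }
  top2 <- new("Topology", atoms = at2, residues = res2, chains = top@chains)
  coords2 <- lapply(seq_len(nFrames(traj)), function(f)
    rbind(traj@coords[[f]], hpos[[f]][needs, , drop = FALSE]))
  new("Trajectory", topology = top2, coords = coords2, box = traj@box,
      time = traj@time)
}
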