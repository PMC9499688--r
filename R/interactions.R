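# Geometric interaction detectors: heavy-atom contacts (0.54 nm), geometric
# hydrogen bonds (D-A < 0.35 nm and D-H-A > 150 deg), inter-peptide contact
# maps, and ligand binding statistics.

CONTACT_CUTOFF <- 0.54
HBOND_DIST <- 0.35
HBOND_ANGLE <- 150

residueSubsetAtoms <- function(topology, resIdx, subset = c("heavy", "MC", "SC")) {
  subset <- match.arg(subset)
  r <- topology@residues[[resIdx]]
  switch(subset, heavy = c(r$backbone, r$sidechain), MC = r$backbone,
         SC = r$sidechain)
}

#' Heavy-atom contact between two residues
#'
#' Two residues are in contact when any pair of their (selected) heavy
#' atoms comes within the cutoff; hydrogens never participate. Distances
#' honour the frame's periodic box.
#'
#' @param traj a [Trajectory-class].
#' @param resA,resB residue indices.
#' @param frame frame index.
#' @param cutoff contact cutoff in nm (default 0.54).
#' @param subset which heavy atoms participate: all (\code{"heavy"}),
#'   main chain (\code{"MC"}) or side chain (\code{"SC"}).
#' @return logical.
#' @export
residueContact <- function(traj, resA, resB, frame = 1L, cutoff = CONTACT_CUTOFF,
                           subset = c("heavy", "MC", "SC")) {
  subset <- match.arg(subset)
  top <- traj@topology
  ia <- residueSubsetAtoms(top, resA, subset)
  ib <- residueSubsetAtoms(top, resB, subset)
  if (!length(ia) || !length(ib)) {
    message(sprintf("residueContact: empty %s atom set (residues %d/%d)",
                    subset, resA, resB))
    return(FALSE)
  }
  x <- traj@coords[[frame]]
  box <- traj@box[[frame]]
  d <- cpp_group_min_dist(x[ia, , drop = FALSE], rep(1L, length(ia)), 1L,
                          x[ib, , drop = FALSE], rep(1L, length(ib)), 1L,
                          if (is.null(box)) numeric(0) else box)
  d[1, 1] <= cutoff
}

# amino-acid (non-cap) residue indices of every peptide chain, as a list
peptideChainResidues <- function(topology) {
  pep <- topology@chains$id[topology@chains$kind == "peptide"]
  out <- lapply(pep, function(cid)
    which(vapply(topology@residues, function(r)
      r$chainId == cid && !isCapName(r$name), TRUE)))
  names(out) <- pep
  out
}

residueLabels <- function(topology, resIdx) {
  paste0(oneLetterOf(vapply(resIdx, function(ri) topology@residues[[ri]]$name, "")),
         vapply(resIdx, function(ri) as.integer(topology@residues[[ri]]$seqNumber), 1L))
}

#' Inter-peptide residue contact probability map
#'
#' Entry (i, j) is the fraction, over frames and ordered chain pairs, of
#' events in which residue position i of one chain and position j of the
#' other are in contact. Averaging over ordered pairs symmetrises the
#' (i, j) and (j, i) contributions of each unordered pair.
#'
#' @param traj a [Trajectory-class] with at least two peptide chains of
#'   identical length.
#' @param contactClass \code{"MC-MC"} or \code{"SC-SC"}.
#' @param cutoff contact cutoff in nm.
#' @return a [ContactMap-class].
#' @export
interpeptideContactMap <- function(traj, contactClass = c("MC-MC", "SC-SC"),
                                   cutoff = CONTACT_CUTOFF) {
  contactClass <- match.arg(contactClass)
  subset <- if (contactClass == "MC-MC") "MC" else "SC"
  top <- traj@topology
  chains <- peptideChainResidues(top)
  if (length(chains) < 2)
    stop("interpeptideContactMap: need at least two peptide chains")
  L <- unique(vapply(chains, length, 1L))
  if (length(L) != 1)
    stop("interpeptideContactMap: peptide chains have unequal residue counts")
  groups <- lapply(chains, function(resIdx) {
    ai <- integer(0); gi <- integer(0)
    for (k in seq_along(resIdx)) {
      a <- residueSubsetAtoms(top, resIdx[k], subset)
      ai <- c(ai, a); gi <- c(gi, rep(k, length(a)))
    }
    list(atoms = ai, gid = gi)
  })
  nf <- nFrames(traj)
  acc <- matrix(0, L, L)
  nPairsOrdered <- 0L
  cids <- seq_along(chains)
  for (f in seq_len(nf)) {
    x <- traj@coords[[f]]
    box <- traj@box[[f]]
    bx <- if (is.null(box)) numeric(0) else box
    for (p in cids) for (q in cids) {
      if (p >= q) next
      gp <- groups[[p]]; gq <- groups[[q]]
      d <- cpp_group_min_dist(x[gp$atoms, , drop = FALSE], gp$gid, L,
                              x[gq$atoms, , drop = FALSE], gq$gid, L, bx)
      hit <- (d <= cutoff)
      acc <- acc + hit + t(hit)   # both orientations of the unordered pair
    }
  }
  nPairs <- length(cids) * (length(cids) - 1L) / 2L
  probs <- acc / (nf * 2 * nPairs)
  probs <- (probs + t(probs)) / 2  # exact symmetry against roundoff
  labels <- residueLabels(top, chains[[1]])
  dimnames(probs) <- list(labels, labels)
  new("ContactMap", labels = labels, probabilities = probs,
      contactClass = contactClass, nFrames = as.integer(nf),
      nChainPairs = as.integer(nPairs))
}

# donor/acceptor tables used by detectHBonds
hbondParticipants <- function(topology) {
  at <- topology@atoms
  dHeavy <- integer(0); dH <- integer(0); dRes <- integer(0)
  aAtom <- integer(0); aRes <- integer(0)
  for (ri in seq_along(topology@residues)) {
    r <- topology@residues[[ri]]
    if (!is.null(r$donors) && nrow(r$donors)) {
      dHeavy <- c(dHeavy, r$donors[, 1]); dH <- c(dH, r$donors[, 2])
      dRes <- c(dRes, rep(ri, nrow(r$donors)))
    }
    if (length(r$acceptors)) {
      aAtom <- c(aAtom, r$acceptors); aRes <- c(aRes, rep(ri, length(r$acceptors)))
    }
  }
  kindOf <- function(ri) {
    topology@chains$kind[match(topology@residues[[ri]]$chainId, topology@chains$id)]
  }
  chainOf <- function(ri) topology@residues[[ri]]$chainId
  isMC <- function(atom, ri) atom %in% topology@residues[[ri]]$backbone
  list(
    donors = data.frame(heavy = dHeavy, hydrogen = dH, res = dRes,
                        chain = vapply(dRes, chainOf, ""),
                        kind = vapply(dRes, kindOf, ""),
                        mc = mapply(isMC, dHeavy, dRes)),
    acceptors = data.frame(atom = aAtom, res = aRes,
                           chain = vapply(aRes, chainOf, ""),
                           kind = vapply(aRes, kindOf, ""),
                           mc = mapply(isMC, aAtom, aRes)))
}

#' Detect geometric hydrogen bonds
#'
#' A hydrogen bond is recorded for every annotated (donor heavy atom,
#' hydrogen, acceptor) triple with donor--acceptor distance below 0.35 nm
#' and D-H-A angle above 150 degrees. Backbone amide hydrogens missing
#' from the topology are reconstructed on the fly; other donors lacking
#' their hydrogen are skipped with a warning at annotation time.
#' Self-bonds within one residue are excluded.
#'
#' @param traj a [Trajectory-class].
#' @param frames frame indices (default all).
#' @param scope \code{"peptide"} for bonds within the peptide set,
#'   \code{"peptide-ligand"} for bonds between a peptide and a ligand
#'   partner.
#' @param distanceCutoff,angleCutoff the geometric criteria (nm, degrees).
#' @return data.frame with columns \code{frame}, \code{donorHeavy},
#'   \code{hydrogen} (NA when reconstructed), \code{acceptor},
#'   \code{donorRes}, \code{acceptorRes}, \code{distanceDA},
#'   \code{angleDHA}, \code{class}.
#' @export
detectHBonds <- function(traj, frames = seq_len(nFrames(traj)),
                         scope = c("peptide", "peptide-ligand"),
                         distanceCutoff = HBOND_DIST, angleCutoff = HBOND_ANGLE) {
  scope <- match.arg(scope)
  top <- traj@topology
  parts <- hbondParticipants(top)
  don <- parts$donors; acc <- parts$acceptors
  if (scope == "peptide") {
    don <- don[don$kind == "peptide", , drop = FALSE]
    acc <- acc[acc$kind == "peptide", , drop = FALSE]
  }
  out <- list()
  for (f in frames) {
    x <- traj@coords[[f]]
    box <- traj@box[[f]]
    hvirt <- amideHydrogenPositions(top, x, warn = FALSE)
    H <- matrix(NA_real_, nrow(don), 3)
    hasH <- !is.na(don$hydrogen)
    H[hasH, ] <- x[don$hydrogen[hasH], , drop = FALSE]
    H[!hasH, ] <- hvirt[don$res[!hasH], , drop = FALSE]
    ok <- is.finite(H[, 1])
    D <- x[don$heavy, , drop = FALSE]
    A <- x[acc$atom, , drop = FALSE]
    nd <- nrow(don); na <- nrow(acc)
    for (ai in seq_len(na)) {
      dv <- sweep(D, 2, A[ai, ], "-") * -1          # D -> A
      dv <- wrapDisplacements(dv, box)
      dDA <- sqrt(rowSums(dv^2))
      cand <- which(ok & dDA < distanceCutoff & don$res != acc$res[ai])
      if (scope == "peptide-ligand") {
        cand <- cand[(don$kind[cand] == "peptide") != (acc$kind[ai] == "peptide")]
      }
      if (!length(cand)) next
      Aw <- D[cand, , drop = FALSE] + dv[cand, , drop = FALSE]  # min-image A
      u <- D[cand, , drop = FALSE] - H[cand, , drop = FALSE]
      v <- Aw - H[cand, , drop = FALSE]
      cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      keep <- which(ang > angleCutoff)
      for (k in keep) {
        i <- cand[k]
        cls <- if (don$kind[i] != acc$kind[ai] ||
                   don$kind[i] == "ligand") "peptide-ligand"
               else if (don$mc[i] && acc$mc[ai]) "MC-MC"
               else if (!don$mc[i] && !acc$mc[ai]) "SC-SC"
               else "MC-SC"
        out[[length(out) + 1L]] <- data.frame(
          frame = f, donorHeavy = don$heavy[i],
          hydrogen = ifelse(hasH[i], don$hydrogen[i], NA_integer_),
          acceptor = acc$atom[ai], donorRes = don$res[i],
          acceptorRes = acc$res[ai], distanceDA = dDA[i], angleDHA = ang[k],
          class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), donorHeavy = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      donorRes = integer(0), acceptorRes = integer(0),
                      distanceDA = numeric(0), angleDHA = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Discrete PDF of per-frame inter-peptide hydrogen-bond counts
#'
#' Counts, per frame, the hydrogen bonds between different peptide chains
#' whose donor and acceptor heavy atoms are both main chain
#' (\code{class = "MC"}) or both side chain (\code{class = "SC"}), and
#' normalises the histogram of counts.
#'
#' @param traj a [Trajectory-class].
#' @param class \code{"MC"} or \code{"SC"}.
#' @param hbonds optional precomputed [detectHBonds()] table (scope
#'   \code{"peptide"}).
#' @return data.frame with columns \code{count} and \code{probability}
#'   (summing to one).
#' @export
hbondCountPdf <- function(traj, class = c("MC", "SC"), hbonds = NULL) {
  class <- match.arg(class)
  want <- if (class == "MC") "MC-MC" else "SC-SC"
  if (is.null(hbonds)) hbonds <- detectHBonds(traj, scope = "peptide")
  top <- traj@topology
  chainOf <- vapply(top@residues, function(r) r$chainId, "")
  sel <- hbonds$class == want &
    chainOf[hbonds$donorRes] != chainOf[hbonds$acceptorRes]
  counts <- tabulate(hbonds$frame[sel], nbins = nFrames(traj))
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)),
             probability = as.numeric(tab) / nFrames(traj))
}

ligandHeavyAtoms <- function(topology) {
  lig <- topology@chains$id[topology@chains$kind == "ligand"]
  if (!length(lig)) stop("no ligand chains in topology")
  unlist(lapply(which(vapply(topology@residues, function(r)
    r$chainId %in% lig, TRUE)), function(ri)
      residueSubsetAtoms(topology, ri, "heavy")))
}

#' Ligand binding probability per residue position
#'
#' For residue position k, the fraction of (frame, peptide chain) pairs
#' in which at least one ligand heavy atom lies within the cutoff of at
#' least one heavy atom of that chain's residue k. With
#' \code{perCopy = TRUE} the denominator is (frame, chain, ligand copy)
#' triples instead.
#'
#' @param traj a [Trajectory-class] containing ligand chains.
#' @param cutoff contact cutoff in nm (default 0.54).
#' @param perCopy normalise per ligand copy instead of per chain.
#' @return data.frame with columns \code{label} and \code{probability}.
#' @export
ligandBindingProbability <- function(traj, cutoff = CONTACT_CUTOFF,
                                     perCopy = FALSE) {
  top <- traj@topology
  chains <- peptideChainResidues(top)
  L <- unique(vapply(chains, length, 1L))
  if (length(L) != 1)
    stop("ligandBindingProbability: peptide chains have unequal residue counts")
  ligChains <- top@chains$id[top@chains$kind == "ligand"]
  if (!length(ligChains)) stop("ligandBindingProbability: no ligand chains")
  ligRes <- which(vapply(top@residues, function(r) r$chainId %in% ligChains, TRUE))
  ligGroups <- if (perCopy) {
    lapply(ligRes, function(ri) residueSubsetAtoms(top, ri, "heavy"))
  } else {
    list(unlist(lapply(ligRes, function(ri) residueSubsetAtoms(top, ri, "heavy"))))
  }
  pepGroups <- lapply(chains, function(resIdx) {
    ai <- integer(0); gi <- integer(0)
    for (k in seq_along(resIdx)) {
      a <- residueSubsetAtoms(top, resIdx[k], "heavy")
      ai <- c(ai, a); gi <- c(gi, rep(k, length(a)))
    }
    list(atoms = ai, gid = gi)
  })
  nf <- nFrames(traj)
  hits <- numeric(L)
  denom <- 0L
  for (f in seq_len(nf)) {
    x <- traj@coords[[f]]
    bx <- if (is.null(traj@box[[f]])) numeric(0) else traj@box[[f]]
    for (g in pepGroups) {
      for (la in ligGroups) {
        d <- cpp_group_min_dist(x[g$atoms, , drop = FALSE], g$gid, L,
                                x[la, , drop = FALSE],
                                rep(1L, length(la)), 1L, bx)
        hits <- hits + (d[, 1] <= cutoff)
        denom <- denom + 1L
      }
    }
  }
  data.frame(label = residueLabels(top, chains[[1]]),
             probability = hits / denom)
}

#' Average peptide--ligand hydrogen bonds per residue position
#'
#' Per-frame average count of peptide-ligand hydrogen bonds whose peptide
#' partner heavy atom is main chain (resp. side chain) of residue
#' position k, summed over chains and ligand copies.
#'
#' @param traj a [Trajectory-class] with annotated ligand donors and
#'   acceptors.
#' @return data.frame with columns \code{label}, \code{mc}, \code{sc}.
#' @export
ligandHbondProfile <- function(traj) {
  top <- traj@topology
  chains <- peptideChainResidues(top)
  L <- length(chains[[1]])
  posOf <- rep(NA_integer_, length(top@residues))
  for (resIdx in chains) posOf[resIdx] <- seq_along(resIdx)
  hb <- detectHBonds(traj, scope = "peptide-ligand")
  mc <- sc <- numeric(L)
  if (nrow(hb)) {
    kindOf <- function(ri) top@chains$kind[match(top@residues[[ri]]$chainId,
                                                 top@chains$id)]
    for (k in seq_len(nrow(hb))) {
      pepRes <- if (kindOf(hb$donorRes[k]) == "peptide") hb$donorRes[k]
                else hb$acceptorRes[k]
      pepAtom <- if (kindOf(hb$donorRes[k]) == "peptide") hb$donorHeavy[k]
                 else hb$acceptor[k]
      pos <- posOf[pepRes]
      if (is.na(pos)) next   # cap residue partner: outside the 10 positions
      if (pepAtom %in% top@residues[[pepRes]]$backbone) {
        mc[pos] <- mc[pos] + 1
      } else {
        sc[pos] <- sc[pos] + 1
      }
    }
  }
  data.frame(label = residueLabels(top, chains[[1]]),
             mc = mc / nFrames(traj), sc = sc / nFrames(traj))
}
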