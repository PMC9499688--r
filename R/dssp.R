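# Kabsch-Sander secondary-structure assignment ("DSSP-lite"): backbone
# hydrogen bonds by the electrostatic energy model, n-turns and helices,
# parallel/antiparallel bridges and ladders, bends, and the classic
# eight-state code mapped to the six reported categories.

KS_COUPLING <- 0.084 * 332   # kcal/mol * Angstrom, = 27.888
KS_CUTOFF <- -0.5            # kcal/mol

#' Kabsch--Sander hydrogen-bond energy between two residues
#'
#' \eqn{E = 0.084 \cdot 332 \, (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' kcal/mol with distances in Angstrom; a backbone hydrogen bond is
#' assigned when \eqn{E < -0.5} kcal/mol.
#'
#' @param traj a [Trajectory-class].
#' @param donorRes,acceptorRes residue indices (donor contributes N,H;
#'   acceptor contributes C,O).
#' @param frame frame index.
#' @return energy in kcal/mol.
#' @export
kabschSanderEnergy <- function(traj, donorRes, acceptorRes, frame = 1L) {
  if (donorRes == acceptorRes)
    stop("kabschSanderEnergy: donor and acceptor must be distinct residues")
  top <- traj@topology
  x <- traj@coords[[frame]]
  getAtom <- function(ri, nm) {
    r <- top@residues[[ri]]
    i <- r$atoms[top@atoms$name[r$atoms] == nm]
    if (!length(i))
      stop(sprintf("kabschSanderEnergy: residue %s%d lacks atom %s",
                   r$name, r$seqNumber, nm))
    x[i[1], ]
  }
  N <- getAtom(donorRes, "N")
  hmat <- amideHydrogenPositions(top, x, warn = FALSE)
  H <- hmat[donorRes, ]
  if (!all(is.finite(H)))
    stop(sprintf("kabschSanderEnergy: residue %d lacks atom H", donorRes))
  C <- getAtom(acceptorRes, "C")
  O <- getAtom(acceptorRes, "O")
  ksEnergy(N, H, C, O)
}

ksEnergy <- function(N, H, C, O) {
  d <- function(a, b) 10 * sqrt(sum((a - b)^2))  # nm -> Angstrom
  KS_COUPLING * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

# Metadata of the peptide amino-acid residues used for assignment
ssResidueTable <- function(topology) {
  keep <- which(vapply(seq_along(topology@residues), function(ri) {
    r <- topology@residues[[ri]]
    kind <- topology@chains$kind[match(r$chainId, topology@chains$id)]
    kind == "peptide" && !isCapName(r$name)
  }, TRUE))
  at <- topology@atoms
  idx <- function(ri, nm) {
    i <- topology@residues[[ri]]$atoms
    i <- i[at$name[i] == nm]
    if (length(i)) i[1] else NA_integer_
  }
  data.frame(res = keep,
             chain = vapply(keep, function(ri) topology@residues[[ri]]$chainId, ""),
             seq = vapply(keep, function(ri)
               as.integer(topology@residues[[ri]]$seqNumber), 1L),
             name = vapply(keep, function(ri) topology@residues[[ri]]$name, ""),
             N = vapply(keep, idx, 1L, nm = "N"),
             CA = vapply(keep, idx, 1L, nm = "CA"),
             C = vapply(keep, idx, 1L, nm = "C"),
             O = vapply(keep, idx, 1L, nm = "O"),
             stringsAsFactors = FALSE)
}

#' Assign secondary structure (Kabsch--Sander rules)
#'
#' Per frame: all backbone hydrogen bonds are found with the
#' Kabsch--Sander energy criterion (amide hydrogens reconstructed where
#' absent); n-turns (i -> i+3, 4, 5) give G/H/I where two consecutive
#' turns overlap and T otherwise; parallel and antiparallel bridge
#' patterns give B, with ladders of two or more consecutive bridges giving
#' E; a bend S is set where the CA(i-2), CA(i), CA(i+2) angle exceeds 70
#' degrees. Codes are resolved with priority H > E > B > G > I > T > S >
#' C; termini lacking context default to C, as do chains shorter than
#' three residues.
#'
#' @param traj a [Trajectory-class].
#' @return a [SecondaryStructure-class] (frames x peptide residues).
#' @export
assignSecondaryStructure <- function(traj) {
  top <- traj@topology
  tab <- ssResidueTable(top)
  n <- nrow(tab)
  if (n == 0) stop("assignSecondaryStructure: no peptide residues")
  nf <- nFrames(traj)
  codes <- matrix("C", nf, n)
  sameChain <- outer(tab$chain, tab$chain, "==")
  # position within chain: i +/- k moves are only valid inside one chain
  follows <- function(i, k) {
    j <- i + k
    ok <- j >= 1 & j <= n
    ok[ok] <- tab$chain[j[ok]] == tab$chain[i[ok]]
    ifelse(ok, j, NA_integer_)
  }
  for (f in seq_len(nf)) {
    x <- traj@coords[[f]]
    hmat <- amideHydrogenPositions(top, x, warn = FALSE)
    hb <- ksHbondMatrix(x, hmat, tab, sameChain)
    codes[f, ] <- ssOneFrame(x, hb, tab, follows, n)
  }
  labels <- paste0(oneLetterOf(tab$name), tab$seq)
  new("SecondaryStructure", codes = codes, residueIndex = as.integer(tab$res),
      labels = labels)
}

oneLetterOf <- function(threeLetterNames) {
  map <- c(ALA = "A", GLY = "G", SER = "S", ASN = "N", PHE = "F", ILE = "I",
           LEU = "L", VAL = "V", THR = "T", CYS = "C", MET = "M", PRO = "P",
           ASP = "D", GLU = "E", GLN = "Q", LYS = "K", ARG = "R", HIS = "H",
           TRP = "W", TYR = "Y")
  out <- map[threeLetterNames]
  out[is.na(out)] <- "X"
  as.character(out)
}

# logical n x n matrix: hb[d, a] TRUE if N-H of residue d donates to C=O of
# residue a (E < -0.5 kcal/mol). CA-CA prescreen at 0.9 nm.
ksHbondMatrix <- function(x, hmat, tab, sameChain) {
  n <- nrow(tab)
  ca <- x[tab$CA, , drop = FALSE]
  dca <- as.matrix(stats::dist(ca))
  hb <- matrix(FALSE, n, n)
  hasH <- is.finite(hmat[tab$res, 1]) & !is.na(tab$N)
  hasCO <- !is.na(tab$C) & !is.na(tab$O)
  cand <- which(dca < 0.9 & !diag(n), arr.ind = TRUE)
  if (!nrow(cand)) return(hb)
  cand <- cand[hasH[cand[, 1]] & hasCO[cand[, 2]], , drop = FALSE]
  if (!nrow(cand)) return(hb)
  d <- cand[, 1]; a <- cand[, 2]
  ang <- function(P, Q) 10 * sqrt(rowSums((P - Q)^2))
  Np <- x[tab$N[d], , drop = FALSE]; Hp <- hmat[tab$res[d], , drop = FALSE]
  Cp <- x[tab$C[a], , drop = FALSE]; Op <- x[tab$O[a], , drop = FALSE]
  E <- KS_COUPLING * (1 / ang(Op, Np) + 1 / ang(Cp, Hp) -
                      1 / ang(Op, Hp) - 1 / ang(Cp, Np))
  hb[cand[E < KS_CUTOFF, , drop = FALSE]] <- TRUE
  hb
}

ssOneFrame <- function(x, hb, tab, follows, n) {
  turnFlag <- matrix(FALSE, n, 3)  # 3-, 4-, 5-turns starting at i
  for (k in 3:5) {
    j <- follows(seq_len(n), k)
    ok <- !is.na(j)
    turnFlag[ok, k - 2] <- hb[cbind(j[ok], which(ok))]
  }
  helixH <- helixG <- helixI <- rep(FALSE, n)
  markHelix <- function(flagCol, span) {
    out <- rep(FALSE, n)
    if (n < 2) return(out)
    for (i in 2:n) {
      prev <- follows(i, -1L)
      if (!is.na(prev) && turnFlag[prev, flagCol] && turnFlag[i, flagCol]) {
        run <- i + 0:(span - 1)
        run <- run[run <= n & !is.na(follows(rep(i, length(run)), run - i))]
        out[run] <- TRUE
      }
    }
    out
  }
  helixG <- markHelix(1, 3)
  helixH <- markHelix(2, 4)
  helixI <- markHelix(3, 5)

  turnT <- rep(FALSE, n)
  for (k in 3:5) {
    for (i in which(turnFlag[, k - 2])) {
      span <- i + seq_len(k - 1)
      span <- span[span <= n & !is.na(follows(rep(i, length(span)), span - i))]
      turnT[span] <- TRUE
    }
  }

  # bridges
  bridgeP <- matrix(FALSE, n, n)
  bridgeA <- matrix(FALSE, n, n)
  im1 <- follows(seq_len(n), -1L); ip1 <- follows(seq_len(n), 1L)
  HB <- function(i, j) {
    ok <- !is.na(i) & !is.na(j)
    out <- rep(FALSE, length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  for (i in seq_len(n)) {
    js <- which(abs(seq_len(n) - i) > 2 | tab$chain != tab$chain[i])
    if (!length(js)) next
    iv <- rep(i, length(js))
    p <- (HB(js, im1[iv]) & HB(ip1[iv], js)) |
         (HB(iv, im1[js]) & HB(ip1[js], iv))
    a <- (HB(iv, js) & HB(js, iv)) |
         (HB(im1[iv], ip1[js]) & HB(im1[js], ip1[iv]))
    bridgeP[i, js] <- p
    bridgeA[i, js] <- a
  }
  bridgeAny <- bridgeP | bridgeA
  isE <- rep(FALSE, n); isB <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in which(bridgeAny[i, ])) {
      ladder <-
        (!is.na(ip1[i]) && !is.na(ip1[j]) && bridgeP[i, j] && bridgeP[ip1[i], ip1[j]]) ||
        (!is.na(im1[i]) && !is.na(im1[j]) && bridgeP[i, j] && bridgeP[im1[i], im1[j]]) ||
        (!is.na(ip1[i]) && !is.na(im1[j]) && bridgeA[i, j] && bridgeA[ip1[i], im1[j]]) ||
        (!is.na(im1[i]) && !is.na(ip1[j]) && bridgeA[i, j] && bridgeA[im1[i], ip1[j]])
      if (ladder) isE[i] <- TRUE else isB[i] <- TRUE
    }
  }
  isB <- isB & !isE

  # bends
  bendS <- rep(FALSE, n)
  for (i in seq_len(n)) {
    a <- follows(i, -2L); b <- follows(i, 2L)
    if (is.na(a) || is.na(b)) next
    u <- x[tab$CA[i], ] - x[tab$CA[a], ]
    v <- x[tab$CA[b], ] - x[tab$CA[i], ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(min(1, max(-1, cosang))) * 180 / pi > 70) bendS[i] <- TRUE
  }

  # chain-length guard: chains shorter than 3 residues stay coil
  shortChain <- tab$chain %in% names(which(table(tab$chain) < 3))

  code <- rep("C", n)
  code[bendS] <- "S"
  code[turnT] <- "T"
  code[helixI] <- "I"
  code[helixG] <- "G"
  code[isB] <- "B"
  code[isE] <- "E"
  code[helixH] <- "H"
  code[shortChain] <- "C"
  code
}

#' Secondary-structure category populations
#'
#' Fractions of (frame, residue) cells per category, overall or per
#' residue position, with standard errors over equal trajectory blocks.
#'
#' @param assignment a [SecondaryStructure-class].
#' @param perResidue if \code{TRUE}, per-position category fractions.
#' @param nBlocks number of equal blocks for the standard error (default
#'   5); blocks need at least one frame each.
#' @return a data.frame with columns \code{category}, \code{fraction},
#'   \code{se} (plus \code{label} in per-residue mode). Fractions sum to
#'   one (per position).
#' @export
ssPopulation <- function(assignment, perResidue = FALSE, nBlocks = 5L) {
  cats <- ssCategories(assignment)
  lev <- ssCategoryNames()
  nf <- nrow(cats)
  nBlocks <- max(1L, min(nBlocks, nf))
  blk <- if (nBlocks > 1) cut(seq_len(nf), nBlocks, labels = FALSE)
         else rep(1L, nf)
  fracOf <- function(m) {
    tab <- table(factor(m, levels = lev))
    as.numeric(tab) / length(m)
  }
  seOf <- function(sub) {
    if (nBlocks < 2) return(rep(NA_real_, length(lev)))
    bf <- vapply(seq_len(nBlocks), function(b)
      fracOf(sub[blk == b, , drop = FALSE]), numeric(length(lev)))
    apply(bf, 1, stats::sd) / sqrt(nBlocks)
  }
  if (!perResidue) {
    data.frame(category = lev, fraction = fracOf(cats), se = seOf(cats),
               stringsAsFactors = FALSE)
  } else {
    # pool equivalent residue positions across chains (identical labels)
    labs <- unique(assignment@labels)
    out <- lapply(labs, function(lb) {
      sub <- cats[, assignment@labels == lb, drop = FALSE]
      data.frame(label = lb, category = lev,
                 fraction = fracOf(sub), se = seOf(sub),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}
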