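# Deterministic synthetic-ensemble generator. A conformer-mixture model
# stands in for replica-exchange sampling: per frame, each peptide chain is
# a beta-sheet-pair member, a helix, or a random-dihedral coil, with state
# probabilities calibrated so the pipeline-measured category fractions hit
# the requested composition targets (e.g. 16% beta-sheet / 52% coil for
# the apo octamer, 2% / 60% with ligand present).

#' Scenario specification for the ensemble generator
#'
#' @param nPeptides number of peptide chains (default 8, the octamer).
#' @param nLigands number of ligand copies (default 4 per peptide, the
#'   1:4 peptide:ligand molar ratio; 0 for the apo system).
#' @param composition named fractions for \code{"beta-sheet"} and
#'   \code{"coil"} (remainder filled by helix/turn/bend byproducts);
#'   fractions must sum to at most 1.
#' @param ligandPlacement \code{"random"} (random pose at least 2 nm from
#'   every peptide atom) or a list \code{list(type = "stacked", angle,
#'   distance)} placing one ligand per phenylalanine ring at the
#'   prescribed stacking geometry (remaining copies random).
#' @param nFrames number of frames.
#' @param noiseSigma isotropic Gaussian coordinate noise, nm (default
#'   0.005).
#' @param sequence peptide sequence (default \code{"SNNFGAILSS"}).
#' @param seqStart author numbering of the first residue (default 20).
#' @param seed RNG seed; identical (spec, seed) gives identical output.
#' @return a \code{scenarioSpec} list.
#' @export
scenarioSpec <- function(nPeptides = 8L, nLigands = 4L * nPeptides,
                         composition = c("beta-sheet" = 0.16, coil = 0.52),
                         ligandPlacement = "random", nFrames = 100L,
                         noiseSigma = 0.005, sequence = "SNNFGAILSS",
                         seqStart = 20L, seed = 1L) {
  stopifnot(nPeptides >= 1, nLigands >= 0, nFrames >= 1, noiseSigma >= 0)
  comp <- c(`beta-sheet` = 0, coil = 0)
  comp[names(composition)] <- composition
  if (!all(names(composition) %in% c("beta-sheet", "coil")))
    stop("scenarioSpec: composition targets must be beta-sheet and/or coil")
  if (sum(comp) > 1 + 1e-9)
    stop("scenarioSpec: composition fractions must sum to at most 1")
  structure(list(nPeptides = as.integer(nPeptides),
                 nLigands = as.integer(nLigands), composition = comp,
                 ligandPlacement = ligandPlacement,
                 nFrames = as.integer(nFrames), noiseSigma = noiseSigma,
                 sequence = sequence, seqStart = as.integer(seqStart),
                 seed = as.integer(seed)),
            class = "scenarioSpec")
}

# category-fraction yields of one conformer (cells = chain residues)
ssYield <- function(traj) {
  ss <- assignSecondaryStructure(traj)
  cats <- factor(ssCategories(ss), levels = ssCategoryNames())
  as.numeric(table(cats)) / length(cats)
}

# yield under the generator's own coordinate noise, averaged over draws:
# edge hydrogen bonds are marginal, so noiseless yields would overestimate
# the realized beta fraction
noisyYield <- function(traj, sigma, nDraws = 40L) {
  if (sigma <= 0) return(ssYield(traj))
  x0 <- traj@coords[[1]]
  acc <- 0
  for (k in seq_len(nDraws)) {
    tr <- traj
    tr@coords <- list(x0 + matrix(stats::rnorm(length(x0), 0, sigma),
                                  nrow(x0), 3))
    acc <- acc + ssYield(tr)
  }
  acc / nDraws
}

# Calibrate chain-state probabilities (sheet member, coil, helix) so the
# expected measured beta-sheet and coil cell fractions match the targets.
calibrateStates <- function(spec, templates, nCalibration = 200L) {
  strand <- buildPeptide(spec$sequence, sheetPhiPsi(), seqStart = spec$seqStart,
                         templates = templates)
  pair <- sheetPairCoords(strand)
  dimer <- mergeSystems(list(strand, shiftTraj(strand, pair$shift)))
  ySheet <- noisyYield(dimer, spec$noiseSigma)
  helix <- buildPeptide(spec$sequence, c(-57, -47), seqStart = spec$seqStart,
                        templates = templates)
  yHelix <- noisyYield(helix, spec$noiseSigma)
  yCoilAcc <- 0
  for (k in seq_len(nCalibration)) {
    cc <- coilConformer(strand, spec, templates)
    yCoilAcc <- yCoilAcc + noisyYield(cc, spec$noiseSigma, nDraws = 1L)
  }
  yCoil <- yCoilAcc / nCalibration
  lev <- ssCategoryNames()
  bi <- match("beta-sheet", lev); ci <- match("coil", lev)
  tb <- spec$composition[["beta-sheet"]]; tc <- spec$composition[["coil"]]
  A <- rbind(c(ySheet[bi] - yHelix[bi], yCoil[bi] - yHelix[bi]),
             c(ySheet[ci] - yHelix[ci], yCoil[ci] - yHelix[ci]))
  b <- c(tb - yHelix[bi], tc - yHelix[ci])
  p <- tryCatch(as.numeric(solve(A, b)), error = function(e) c(NA, NA))
  if (any(!is.finite(p))) stop("generateEnsemble: state calibration failed")
  p <- pmin(1, pmax(0, p))
  if (sum(p) > 1) p <- p / sum(p)
  list(pSheet = p[1], pCoil = p[2], pHelix = max(0, 1 - sum(p)),
       strand = strand, helix = helix, pairShift = pair$shift)
}

sheetPairCoords <- function(strand) {
  fr <- strandFrame(strand)
  list(shift = 0.48 * fr$hbond)
}

shiftTraj <- function(traj, shift) {
  out <- traj
  out@coords <- list(sweep(traj@coords[[1]], 2, shift, "+"))
  out
}

# one random-coil conformer: broad non-helix dihedral sampling with
# self-clash rejection (heavy atoms of residues >= 2 apart under 0.2 nm)
coilConformer <- function(strandTemplate, spec, templates, maxTries = 30L) {
  n <- nchar(spec$sequence)
  at <- strandTemplate@topology@atoms
  heavy <- which(!at$isHydrogen)
  ri <- at$resIndex[heavy]
  for (t in seq_len(maxTries)) {
    phi <- runif(n, -160, -50)
    psi <- runif(n, -180, 180)
    tr <- buildPeptide(spec$sequence, cbind(phi, psi), seqStart = spec$seqStart,
                       templates = templates)
    x <- tr@coords[[1]][heavy, , drop = FALSE]
    d <- cpp_group_min_dist(x, ri, max(ri), x, ri, max(ri), numeric(0))
    sep <- abs(outer(seq_len(max(ri)), seq_len(max(ri)), "-")) >= 2
    if (min(d[sep]) >= 0.2) return(tr)
  }
  stop("coilConformer: failed to build a clash-free coil conformer")
}

randomRotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic conformational ensemble
#'
#' Per frame, chain states are drawn from the calibrated state
#' probabilities (sheet pairs are placed as rigid two-chain units), coil
#' chains are rebuilt with fresh random dihedrals, all units are packed
#' into a cubic box without inter-unit clashes (minimum heavy-atom
#' clearance 0.45 nm, so no spurious inter-unit hydrogen bonds arise),
#' ligands are placed per the scenario, and isotropic Gaussian noise is
#' added. The box edge is three times the largest unit extent; output is
#' reproducible bit-for-bit for identical (spec, seed).
#'
#' @param spec a [scenarioSpec()].
#' @param templates residue templates.
#' @return a [Trajectory-class] of \code{spec$nFrames} frames.
#' @export
generateEnsemble <- function(spec, templates = defaultTemplates()) {
  stopifnot(inherits(spec, "scenarioSpec"))
  set.seed(spec$seed)
  cal <- calibrateStates(spec, templates)
  nP <- spec$nPeptides; nL <- spec$nLigands
  ligand <- if (nL > 0) buildLigand(templates = templates) else NULL

  # merged system topology: peptide chains then ligand copies
  parts <- c(rep(list(cal$strand), nP), rep(list(ligand), nL))
  merged <- mergeSystems(parts)
  top <- merged@topology
  atCounts <- vapply(parts, nAtoms, 1L)
  blockEnd <- cumsum(atCounts)
  blockStart <- blockEnd - atCounts + 1L
  pepBlocks <- lapply(seq_len(nP), function(i) blockStart[i]:blockEnd[i])
  ligBlocks <- if (nL > 0)
    lapply(nP + seq_len(nL), function(i) blockStart[i]:blockEnd[i]) else list()

  strandExtent <- max(stats::dist(cal$strand@coords[[1]]))
  boxEdge <- 3 * (strandExtent + 0.48)
  box <- rep(boxEdge, 3)

  pepHeavy <- lapply(seq_len(nP), function(i) {
    b <- pepBlocks[[i]]
    b[!top@atoms$isHydrogen[b]]
  })
  ligHeavyLoc <- if (nL > 0) which(!ligand@topology@atoms$isHydrogen) else integer(0)

  stacked <- is.list(spec$ligandPlacement) &&
    identical(spec$ligandPlacement$type, "stacked")
  pheRingLoc <- ringSelection(cal$strand@topology, "resname PHE")

  nf <- spec$nFrames
  frames <- vector("list", nf)
  clearance <- 0.45
  for (f in seq_len(nf)) {
    nPairs <- stats::rbinom(1, floor(nP / 2), cal$pSheet)
    chainsLeft <- nP - 2 * nPairs
    states <- character(0)
    if (chainsLeft > 0) {
      pc <- if (cal$pCoil + cal$pHelix > 0)
        cal$pCoil / (cal$pCoil + cal$pHelix) else 1
      states <- ifelse(runif(chainsLeft) < pc, "coil", "helix")
    }
    units <- list()   # list of coordinate matrices + chain slots
    slot <- 1L
    if (nPairs > 0) for (k in seq_len(nPairs)) {
      xa <- cal$strand@coords[[1]]
      xb <- sweep(xa, 2, cal$pairShift, "+")
      units[[length(units) + 1L]] <- list(coords = rbind(xa, xb),
                                          chains = c(slot, slot + 1L))
      slot <- slot + 2L
    }
    for (s in states) {
      xc <- if (s == "coil") coilConformer(cal$strand, spec, templates)@coords[[1]]
            else cal$helix@coords[[1]]
      units[[length(units) + 1L]] <- list(coords = xc, chains = slot)
      slot <- slot + 1L
    }
    # pack peptide units
    placed <- list()
    placedHeavy <- NULL
    X <- matrix(NA_real_, nAtoms(merged), 3)
    for (u in units) {
      nAtU <- nrow(u$coords) / length(u$chains)
      hLoc <- which(!top@atoms$isHydrogen[rep(pepBlocks[[u$chains[1]]],
                                              length(u$chains))])
      okPlaced <- FALSE
      for (try in seq_len(200L)) {
        R <- randomRotation()
        ctr <- runif(3, 0.15 * boxEdge, 0.85 * boxEdge)
        xc <- u$coords %*% t(R)
        xc <- sweep(xc, 2, colMeans(xc))
        xc <- sweep(xc, 2, ctr, "+")
        hx <- xc[hLoc, , drop = FALSE]
        if (is.null(placedHeavy) ||
            min(cpp_group_min_dist(hx, rep(1L, nrow(hx)), 1L, placedHeavy,
                                   rep(1L, nrow(placedHeavy)), 1L, box)) >= clearance) {
          for (ci in seq_along(u$chains))
            X[pepBlocks[[u$chains[ci]]], ] <-
              xc[((ci - 1) * nAtU + 1):(ci * nAtU), , drop = FALSE]
          placedHeavy <- rbind(placedHeavy, hx)
          okPlaced <- TRUE
          break
        }
      }
      if (!okPlaced)
        stop("generateEnsemble: packing failed; consider a larger box")
    }
    # ligands
    if (nL > 0) {
      pepAll <- placedHeavy
      nStack <- if (stacked) min(nL, nP) else 0L
      for (l in seq_len(nL)) {
        xl0 <- ligand@coords[[1]]
        okPlaced <- FALSE
        if (l <= nStack) {
          chain <- l  # one stacked copy per chain's phenylalanine ring
          ringIdx <- pepBlocks[[chain]][pheRingLoc[[1]]]
          rg <- ringGeometry(X[ringIdx, , drop = FALSE])
          lt <- placeLigandStacked(ligand, rg, spec$ligandPlacement$angle,
                                   spec$ligandPlacement$distance,
                                   azimuth = runif(1, 0, 360))
          xl <- lt@coords[[1]]
          okPlaced <- TRUE
        } else {
          for (try in seq_len(400L)) {
            R <- randomRotation()
            ctr <- runif(3, 0.05 * boxEdge, 0.95 * boxEdge)
            xl <- xl0 %*% t(R)
            xl <- sweep(xl, 2, colMeans(xl))
            xl <- sweep(xl, 2, ctr, "+")
            hx <- xl[ligHeavyLoc, , drop = FALSE]
            dPep <- min(cpp_group_min_dist(hx, rep(1L, nrow(hx)), 1L, pepAll,
                                           rep(1L, nrow(pepAll)), 1L, box))
            dAll <- min(cpp_group_min_dist(hx, rep(1L, nrow(hx)), 1L,
                                           placedHeavy,
                                           rep(1L, nrow(placedHeavy)), 1L, box))
            if (dPep >= 2.0 && dAll >= clearance) { okPlaced <- TRUE; break }
          }
        }
        if (!okPlaced)
          stop("generateEnsemble: ligand placement failed; consider a larger box")
        X[ligBlocks[[l]], ] <- xl
        placedHeavy <- rbind(placedHeavy, xl[ligHeavyLoc, , drop = FALSE])
      }
    }
    if (spec$noiseSigma > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, spec$noiseSigma), nrow(X), 3)
    frames[[f]] <- X
  }
  new("Trajectory", topology = top, coords = frames,
      box = rep(list(box), nf), time = seq_len(nf) - 1)
}
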