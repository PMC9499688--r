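# Synthetic conformer construction: internal-coordinate peptide builder,
# beta-sheet oligomer assembly, idealized ligand, and prescribed stacking
# placement. These are first-class, deterministic generators that let every
# analysis stage run without a molecular-dynamics engine.

# standard backbone geometry (nm / degrees)
BB <- list(b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329,
           a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7,
           b_CO = 0.1231, a_CACO = 120.5, b_NH = 0.100, omega = 180)

#' Build a capped peptide chain from backbone dihedrals
#'
#' Constructs the backbone by sequential internal-coordinate extension
#' (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A; angles 111.2/116.2/121.7
#' degrees; omega = 180), attaches side chains from the idealized residue
#' templates at their default rotamer, places carbonyl oxygens and amide
#' hydrogens, and adds CH3CO / NH2 terminal caps.
#'
#' @param sequence one-letter residue codes (default \code{"SNNFGAILSS"},
#'   the amyloidogenic core hIAPP 20-29).
#' @param phiPsi n x 2 matrix of (phi, psi) in degrees, or a length-2
#'   vector recycled to all residues.
#' @param caps logical(2): acetyl N-cap, amide C-cap.
#' @param chainId single-character chain identifier.
#' @param seqStart author numbering of the first residue (default 20).
#' @param templates residue templates.
#' @return a single-chain, single-frame [Trajectory-class].
#' @export
buildPeptide <- function(sequence = "SNNFGAILSS", phiPsi = c(-119, 113),
                         caps = c(TRUE, TRUE), chainId = "A", seqStart = 20,
                         templates = defaultTemplates()) {
  resNames <- threeLetter(sequence)
  n <- length(resNames)
  if (n < 2) stop("buildPeptide: sequence needs at least 2 residues")
  if (is.null(dim(phiPsi))) phiPsi <- matrix(phiPsi, n, 2, byrow = TRUE)
  phiPsi <- as.matrix(phiPsi)
  if (nrow(phiPsi) != n || ncol(phiPsi) != 2 || any(!is.finite(phiPsi)))
    stop("buildPeptide: phiPsi must be a finite n x 2 matrix")
  for (rn in resNames) if (is.null(templates[[rn]]))
    stop("buildPeptide: no template for residue ", rn)

  Npos <- CApos <- Cpos <- Opos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(BB$b_NCA, 0, 0)
  th <- (180 - BB$a_NCAC) * pi / 180
  Cpos[1, ] <- CApos[1, ] + BB$b_CAC * c(cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    Npos[i, ] <- placeAtom(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                           BB$b_CN, BB$a_CACN, phiPsi[i - 1, 2])
    CApos[i, ] <- placeAtom(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                            BB$b_NCA, BB$a_CNCA, BB$omega)
    Cpos[i, ] <- placeAtom(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                           BB$b_CAC, BB$a_NCAC, phiPsi[i, 1])
  }
  for (i in seq_len(n))
    Opos[i, ] <- placeAtom(Npos[i, ], CApos[i, ], Cpos[i, ],
                           BB$b_CO, BB$a_CACO, phiPsi[i, 2] - 180)

  aceCoords <- NULL
  if (caps[1]) {
    Cace <- placeAtom(Cpos[1, ], CApos[1, ], Npos[1, ], BB$b_CN, BB$a_CNCA,
                      phiPsi[1, 1])
    CH3 <- placeAtom(CApos[1, ], Npos[1, ], Cace, 0.1520, BB$a_CACN, BB$omega)
    Oace <- placeAtom(CApos[1, ], Npos[1, ], Cace, BB$b_CO, 123.0, 0)
    aceCoords <- rbind(CH3 = CH3, C = Cace, O = Oace)
  }
  nh2Coords <- NULL
  if (caps[2]) {
    Nc <- placeAtom(Npos[n, ], CApos[n, ], Cpos[n, ], BB$b_CN, BB$a_CACN,
                    phiPsi[n, 2])
    HN1 <- placeAtom(CApos[n, ], Cpos[n, ], Nc, 0.101, 120, 180)
    HN2 <- placeAtom(CApos[n, ], Cpos[n, ], Nc, 0.101, 120, 0)
    nh2Coords <- rbind(N = Nc, HN1 = HN1, HN2 = HN2)
  }

  # amide hydrogens in the peptide plane: H-N-C(prev) and H-N-CA both
  # ~120 degrees, trans to the preceding carbonyl oxygen
  Hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    Cprev <- if (i > 1) Cpos[i - 1, ] else if (caps[1]) aceCoords["C", ] else NULL
    if (!is.null(Cprev))
      Hpos[i, ] <- amideHydrogenPlanar(Npos[i, ], CApos[i, ], Cprev)
  }

  # assemble atom table residue by residue
  atomName <- character(0); element <- character(0); resIdx <- integer(0)
  xyz <- NULL
  resInfo <- list()
  addResidue <- function(rname, coordsByName, seqNumber) {
    tpl <- templates[[rname]]
    keep <- names(coordsByName)
    resInfo[[length(resInfo) + 1L]] <<- list(name = rname, seq = seqNumber,
                                             atomNames = keep)
    atomName <<- c(atomName, keep)
    element <<- c(element, tpl$atoms$element[match(keep, tpl$atoms$name)])
    resIdx <<- c(resIdx, rep(length(resInfo), length(keep)))
    xyz <<- rbind(xyz, do.call(rbind, coordsByName))
  }

  if (caps[1]) addResidue("ACE", list(CH3 = aceCoords["CH3", ],
                                      C = aceCoords["C", ],
                                      O = aceCoords["O", ]), seqStart - 1L)
  for (i in seq_len(n)) {
    tpl <- templates[[resNames[i]]]
    res <- list(N = Npos[i, ], CA = CApos[i, ], C = Cpos[i, ], O = Opos[i, ])
    if (all(is.finite(Hpos[i, ]))) res$H <- Hpos[i, ]
    scNames <- tpl$atoms$name[!(tpl$atoms$name %in% c("N", "CA", "C", "O", "H"))]
    if (length(scNames)) {
      tmat <- as.matrix(tpl$atoms[, c("x", "y", "z")])
      rownames(tmat) <- tpl$atoms$name
      fit <- kabschSuperpose(rbind(Npos[i, ], CApos[i, ], Cpos[i, ]),
                             tmat[c("N", "CA", "C"), ])
      moved <- tmat[scNames, , drop = FALSE] %*% t(fit$rotation)
      moved <- sweep(moved, 2, fit$translation, "+")
      for (k in seq_along(scNames)) res[[scNames[k]]] <- moved[k, ]
    }
    addResidue(resNames[i], res, seqStart + i - 1L)
  }
  if (caps[2]) addResidue("NH2", list(N = nh2Coords["N", ],
                                      HN1 = nh2Coords["HN1", ],
                                      HN2 = nh2Coords["HN2", ]),
                          seqStart + n)

  isH <- element == "H"
  atomsDf <- data.frame(serial = seq_along(atomName), name = atomName,
                        element = element, resIndex = resIdx, isHydrogen = isH,
                        mass = elementMass(element), vdw = elementVdw(element),
                        stringsAsFactors = FALSE)
  resRecords <- vector("list", length(resInfo))
  for (ri in seq_along(resInfo)) {
    info <- resInfo[[ri]]
    ai <- which(resIdx == ri)
    resRecords[[ri]] <- residueRecordFromTemplate(
      templates[[info$name]], ai, atomName[ai], chainId, info$seq, isH[ai])
  }
  top <- new("Topology", atoms = atomsDf, residues = resRecords,
             chains = data.frame(id = chainId, kind = "peptide",
                                 stringsAsFactors = FALSE))
  rownames(xyz) <- NULL
  new("Trajectory", topology = top, coords = list(xyz), box = list(NULL),
      time = 0)
}

# H on amide N, 0.10 nm along the normalized sum of the unit vectors
# N->(away from C_prev) and N->(away from O_prev)
amideHydrogenFromContext <- function(N, Cprev, Oprev) {
  u1 <- N - Cprev; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- N - Oprev; u2 <- u2 / sqrt(sum(u2^2))
  u <- u1 + u2
  N + BB$b_NH * u / sqrt(sum(u^2))
}

# builder's amide H: in the sp2 amide plane, opposite the bisector of the
# C(prev)-N-CA angle (standard peptide geometry, trans to the carbonyl O)
amideHydrogenPlanar <- function(N, CA, Cprev) {
  u1 <- Cprev - N; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- CA - N; u2 <- u2 / sqrt(sum(u2^2))
  u <- -(u1 + u2)
  N + BB$b_NH * u / sqrt(sum(u^2))
}

#' Build an idealized ligand
#'
#' Rigid idealized melatonin: planar indole (annotated benzene and pyrrole
#' rings), 5-methoxy group, and the N-acetyl amide side chain (donor N-H,
#' acceptor C=O), realized from the packaged template.
#'
#' @param kind currently only \code{"melatonin"}.
#' @param chainId chain identifier.
#' @param templates residue templates.
#' @return single-residue, single-frame [Trajectory-class] of chain kind
#'   \code{ligand}.
#' @export
buildLigand <- function(kind = "melatonin", chainId = "x",
                        templates = defaultTemplates()) {
  kind <- match.arg(kind)
  tpl <- templates[["MEL"]]
  if (is.null(tpl)) stop("buildLigand: no MEL template")
  xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  isH <- tpl$atoms$element == "H"
  atomsDf <- data.frame(serial = seq_len(nrow(xyz)), name = tpl$atoms$name,
                        element = tpl$atoms$element, resIndex = 1L,
                        isHydrogen = isH, mass = elementMass(tpl$atoms$element),
                        vdw = elementVdw(tpl$atoms$element),
                        stringsAsFactors = FALSE)
  rec <- residueRecordFromTemplate(tpl, seq_len(nrow(xyz)), tpl$atoms$name,
                                   chainId, 1L, isH)
  top <- new("Topology", atoms = atomsDf, residues = list(rec),
             chains = data.frame(id = chainId, kind = "ligand",
                                 stringsAsFactors = FALSE))
  rownames(xyz) <- NULL
  new("Trajectory", topology = top, coords = list(xyz), box = list(NULL),
      time = 0)
}

# benzene-ring atom indices of a ligand residue (its first 6-membered ring)
ligandBenzeneRing <- function(topology, resIdx = 1L) {
  rings <- topology@residues[[resIdx]]$rings
  six <- rings[vapply(rings, length, 1L) == 6L]
  if (!length(six)) stop("ligand residue has no six-membered ring annotation")
  six[[1]]
}

#' Place a ligand at a prescribed stacking geometry
#'
#' Rigidly moves the ligand so that its benzene-ring centroid sits at the
#' given distance along the target ring normal and the interplane angle
#' equals the given angle. The residual azimuthal freedom is fixed
#' deterministically (tilt about a reference axis perpendicular to the
#' target normal, derived from the global x axis).
#'
#' @param ligand single-frame [Trajectory-class] (e.g. [buildLigand()]).
#' @param targetRing a ring geometry from [ringGeometry()].
#' @param angle prescribed interplane angle, degrees in [0, 90].
#' @param centroidDistance prescribed centroid-centroid distance, nm > 0.
#' @param azimuth optional extra rotation about the target normal, degrees.
#' @return the ligand [Trajectory-class] with transformed coordinates.
#' @export
placeLigandStacked <- function(ligand, targetRing, angle, centroidDistance,
                               azimuth = 0) {
  stopifnot(angle >= 0, angle <= 90, centroidDistance > 0)
  ringIdx <- ligandBenzeneRing(ligand@topology)
  x <- ligand@coords[[1]]
  rg <- ringGeometry(x[ringIdx, , drop = FALSE])
  nt <- targetRing$normal / sqrt(sum(targetRing$normal^2))
  # 1) move ligand ring centroid to the origin
  x0 <- sweep(x, 2, rg$centroid)
  # 2) align the ligand ring normal with the target normal
  nl <- rg$normal
  ax <- pracmaCross(nl, nt)
  s <- sqrt(sum(ax^2))
  if (s > 1e-12) {
    R1 <- rotationAboutAxis(ax / s, atan2(s, sum(nl * nt)) * 180 / pi)
  } else if (sum(nl * nt) < 0) {
    perp <- if (abs(nt[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * nt) * nt
    R1 <- rotationAboutAxis(perp / sqrt(sum(perp^2)), 180)
  } else R1 <- diag(3)
  # 3) tilt by the prescribed angle about a deterministic in-plane axis
  e1 <- c(1, 0, 0) - nt[1] * nt
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - nt[2] * nt
  e1 <- e1 / sqrt(sum(e1^2))
  R2 <- rotationAboutAxis(e1, angle)
  R <- R2 %*% R1
  if (azimuth != 0) R <- rotationAboutAxis(nt, azimuth) %*% R
  xr <- x0 %*% t(R)
  target <- targetRing$centroid + centroidDistance * nt
  xr <- sweep(xr, 2, target, "+")
  out <- ligand
  out@coords <- list(xr)
  out
}

#' Merge single-frame systems into one Trajectory
#'
#' Concatenates the chains of several single-frame trajectories into one
#' system, renumbering atom serials and assigning fresh chain identifiers.
#'
#' @param parts list of single-frame [Trajectory-class] objects.
#' @param chainIds optional character vector of new chain ids (one per
#'   part; parts with several chains get suffixes).
#' @param box optional numeric(3) box edges in nm.
#' @return a single-frame [Trajectory-class].
#' @export
mergeSystems <- function(parts, chainIds = NULL, box = NULL) {
  stopifnot(length(parts) >= 1)
  if (is.null(chainIds)) chainIds <- chainAlphabet()[seq_along(parts)]
  atomsL <- list(); resL <- list(); chainsL <- list(); xyzL <- list()
  atomOff <- 0L
  for (p in seq_along(parts)) {
    tr <- parts[[p]]
    top <- tr@topology
    at <- top@atoms
    idMap <- structure(paste0(chainIds[p],
                              if (nrow(top@chains) > 1)
                                seq_len(nrow(top@chains)) else ""),
                       names = top@chains$id)
    chainsL[[p]] <- data.frame(id = unname(idMap), kind = top@chains$kind,
                               stringsAsFactors = FALSE)
    res <- lapply(top@residues, function(r) {
      r$chainId <- unname(idMap[r$chainId])
      r$atoms <- r$atoms + atomOff
      r$backbone <- r$backbone + atomOff
      r$sidechain <- r$sidechain + atomOff
      if (!is.null(r$donors)) r$donors <- r$donors + atomOff
      r$acceptors <- r$acceptors + atomOff
      r$rings <- lapply(r$rings, function(x) x + atomOff)
      r$methyls <- r$methyls + atomOff
      r
    })
    at$resIndex <- at$resIndex + sum(vapply(resL, length, 1L))
    resL[[p]] <- res
    atomsL[[p]] <- at
    xyzL[[p]] <- tr@coords[[1]]
    atomOff <- atomOff + nrow(at)
  }
  atomsDf <- do.call(rbind, atomsL)
  atomsDf$serial <- seq_len(nrow(atomsDf))
  rownames(atomsDf) <- NULL
  top <- new("Topology", atoms = atomsDf, residues = do.call(c, resL),
             chains = do.call(rbind, chainsL))
  new("Trajectory", topology = top, coords = list(do.call(rbind, xyzL)),
      box = list(box), time = 0)
}

chainAlphabet <- function() c(LETTERS, letters, as.character(0:9))

#' Build an in-register beta-sheet oligomer
#'
#' Copies of an extended strand stacked at the given inter-strand spacing,
#' oriented per registry, with the geometry arranged so interior residues
#' of adjacent strands satisfy the Kabsch--Sander backbone hydrogen-bond
#' criterion.
#'
#' @param nStrands number of strands (>= 2).
#' @param sequence one-letter sequence for every strand.
#' @param registry \code{"parallel"} or \code{"antiparallel"}.
#' @param strandSpacing inter-strand spacing in nm (default 0.48).
#' @param chainIds optional chain ids.
#' @param templates residue templates.
#' @return a single-frame [Trajectory-class] with one chain per strand.
#' @export
buildSheetOligomer <- function(nStrands, sequence = "SNNFGAILSS",
                               registry = c("parallel", "antiparallel"),
                               strandSpacing = 0.48, chainIds = NULL,
                               templates = defaultTemplates()) {
  registry <- match.arg(registry)
  if (nStrands < 2) stop("buildSheetOligomer: need at least 2 strands")
  if (strandSpacing <= 0) stop("buildSheetOligomer: spacing must be positive")
  if (is.null(chainIds)) chainIds <- chainAlphabet()[seq_len(nStrands)]
  strand <- buildPeptide(sequence, phiPsi = sheetPhiPsi(), chainId = "A",
                         templates = templates)
  x <- strand@coords[[1]]
  frame <- strandFrame(strand)
  parts <- vector("list", nStrands)
  for (s in seq_len(nStrands)) {
    xi <- x
    if (registry == "antiparallel" && s %% 2 == 0) {
      # flip the strand end-over-end about the H-bond axis
      xi <- sweep(xi, 2, frame$origin)
      xi <- xi %*% t(rotationAboutAxis(frame$hbond, 180))
      xi <- sweep(xi, 2, frame$origin, "+")
      xi <- sweep(xi, 2, sheetAntiShift() * frame$axis, "+")
    }
    xi <- sweep(xi, 2, (s - 1) * strandSpacing * frame$hbond, "+")
    tr <- strand
    tr@coords <- list(xi)
    parts[[s]] <- tr
  }
  mergeSystems(parts, chainIds = chainIds)
}

# dihedrals and registry constants of the sheet builder (frozen after
# tuning against the Kabsch-Sander criterion; see the methods vignette)
sheetPhiPsi <- function() c(-125, 120)
sheetAntiShift <- function() 0

# orthonormal frame of an extended strand: axis (first->last CA), hbond
# direction (mean carbonyl C->O direction, orthogonalized), and origin
strandFrame <- function(strand) {
  top <- strand@topology
  x <- strand@coords[[1]]
  ca <- atomSelect(top, "peptide and name CA")
  axis <- x[ca[length(ca)], ] - x[ca[1], ]
  axis <- axis / sqrt(sum(axis^2))
  cAt <- atomSelect(top, "backbone and name C")
  oAt <- atomSelect(top, "backbone and name O")
  co <- x[oAt, , drop = FALSE] - x[cAt, , drop = FALSE]
  # alternate carbonyls point to opposite sheet neighbours; take the first
  co1 <- colMeans(co[seq(1, nrow(co), by = 2), , drop = FALSE])
  hb <- co1 - sum(co1 * axis) * axis
  hb <- hb / sqrt(sum(hb^2))
  list(axis = axis, hbond = hb, origin = colMeans(x[ca, , drop = FALSE]))
}
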