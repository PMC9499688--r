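# Multi-model PDB is the trajectory interchange format. Record-level parsing
# is delegated to bio3d; this layer adds the per-model atom-count contract,
# CRYST1 box handling, and template-driven role annotation.

#' Read a multi-model PDB file as a Trajectory
#'
#' Each \code{MODEL}/\code{ENDMDL} block (or the single implicit model)
#' becomes one frame; coordinates are converted from Angstrom to nm. A
#' \code{CRYST1} record with 90-degree angles is parsed into an
#' orthorhombic box. Residues are resolved against templates, which attach
#' the backbone/side-chain partition and donor/acceptor/ring/methyl
#' annotations; unknown residue names are an error unless a template is
#' supplied via \code{templates}.
#'
#' @param path PDB file.
#' @param templates named template list, see [defaultTemplates()] and
#'   [readTemplates()].
#' @return a [Trajectory-class].
#' @export
readMultiModelPDB <- function(path, templates = defaultTemplates()) {
  if (!file.exists(path)) stop("readMultiModelPDB: no such file: ", path)
  lines <- readLines(path)
  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    f <- function(i, j) as.numeric(substr(cl[1], i, j))
    edges <- c(f(7, 15), f(16, 24), f(25, 33))
    angles <- c(f(34, 40), f(41, 47), f(48, 54))
    if (any(abs(angles - 90) > 1e-3))
      stop("readMultiModelPDB: only orthorhombic (90/90/90) boxes are supported")
    if (all(is.finite(edges)) && all(edges > 0)) box <- edges * 0.1
  }
  # per-model atom-count contract, checked before handing off to bio3d
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1) {
    modelIdx <- findInterval(which(isAtom), modelStarts)
    counts <- tabulate(modelIdx, nbins = length(modelStarts))
    if (length(unique(counts)) > 1) {
      ref <- counts[1]
      bad <- which(counts != ref)[1]
      stop(sprintf(paste0("readMultiModelPDB: atom count mismatch in model %d ",
                          "(%d atoms, expected %d)"), bad, counts[bad], ref))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz                       # nModels x 3N, Angstrom
  nAt <- nrow(at)
  nModels <- nrow(xyz)

  # residue grouping in file order
  resKey <- paste(at$chain, at$resno, at$insert)
  resBreak <- c(TRUE, resKey[-1] != resKey[-nAt])
  resIndex <- cumsum(resBreak)
  nRes <- resIndex[nAt]

  element <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                   NA, at$elesy)))
  guess <- substr(sub("^[0-9]*", "", trimws(at$elety)), 1, 1)
  element[is.na(element)] <- guess[is.na(element)]
  isH <- element == "H"

  atomsDf <- data.frame(serial = at$eleno, name = trimws(at$elety),
                        element = element, resIndex = resIndex,
                        isHydrogen = isH, mass = elementMass(element),
                        vdw = elementVdw(element), stringsAsFactors = FALSE)

  resRecords <- vector("list", nRes)
  chainIds <- character(0); chainKinds <- character(0)
  unknown <- character(0)
  for (ri in seq_len(nRes)) {
    ai <- which(resIndex == ri)
    rname <- trimws(at$resid[ai[1]])
    tpl <- templates[[rname]]
    if (is.null(tpl)) { unknown <- c(unknown, rname); next }
    chainId <- ifelse(is.na(at$chain[ai[1]]), " ", at$chain[ai[1]])
    if (!chainId %in% chainIds) {
      chainIds <- c(chainIds, chainId)
      chainKinds <- c(chainKinds, if (tpl$kind == "ligand") "ligand" else "peptide")
    }
    resRecords[[ri]] <- residueRecordFromTemplate(
      tpl, ai, atomsDf$name[ai], chainId, at$resno[ai[1]], isH[ai])
  }
  if (length(unknown))
    stop("readMultiModelPDB: unknown residue(s) with no template: ",
         paste(unique(unknown), collapse = ", "))

  top <- new("Topology", atoms = atomsDf, residues = resRecords,
             chains = data.frame(id = chainIds, kind = chainKinds,
                                 stringsAsFactors = FALSE))
  coords <- lapply(seq_len(nModels), function(m)
    matrix(xyz[m, ], ncol = 3, byrow = TRUE) * 0.1)
  new("Trajectory", topology = top, coords = coords,
      box = rep(list(box), nModels), time = seq_len(nModels) - 1)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Emits one \code{MODEL}/\code{ENDMDL} block per frame, coordinates in
#' Angstrom at the format's fixed-width precision (0.001 A, i.e. 0.0001
#' nm), and a \code{CRYST1} record when the first frame carries a box.
#' Reading the file back reproduces coordinates to format precision and
#' all template-derived annotations.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMultiModelPDB <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  top <- traj@topology
  at <- top@atoms
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj@box[[1]]
  if (!is.null(b))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1] * 10, b[2] * 10, b[3] * 10, 90, 90, 90), con)
  resOf <- integer(nrow(at))
  for (ri in seq_along(top@residues)) resOf[top@residues[[ri]]$atoms] <- ri
  resName <- vapply(top@residues, function(r) r$name, "")
  resChain <- vapply(top@residues, function(r) substr(r$chainId, 1, 1), "")
  resSeq <- vapply(top@residues, function(r) as.integer(r$seqNumber), 1L)
  nm <- at$name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- traj@coords[[f]] * 10
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       at$serial %% 100000L, nm4, resName[resOf], resChain[resOf],
                       resSeq[resOf] %% 10000L, x[, 1], x[, 2], x[, 3],
                       1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
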