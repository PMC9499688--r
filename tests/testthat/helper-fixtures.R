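# Shared fixture builders: tiny hand-assembled topologies with full control
# over coordinates, plus cached generated systems.

# A topology of nChains single-residue "peptide" chains, one heavy carbon
# atom each (plus an optional bonded hydrogen), at given coordinates.
pointResidueSystem <- function(coordsList, withHydrogen = FALSE, box = NULL) {
  nC <- length(coordsList)
  atoms <- NULL; residuesL <- list(); xyz <- NULL
  perRes <- if (withHydrogen) 2L else 1L
  for (i in seq_len(nC)) {
    base <- (i - 1L) * perRes
    atoms <- rbind(atoms, data.frame(
      serial = base + 1L, name = "CA", element = "C", resIndex = i,
      isHydrogen = FALSE, mass = 12.011, vdw = 0.17, stringsAsFactors = FALSE))
    x <- matrix(coordsList[[i]], 1, 3)
    if (withHydrogen) {
      atoms <- rbind(atoms, data.frame(
        serial = base + 2L, name = "HA", element = "H", resIndex = i,
        isHydrogen = TRUE, mass = 1.008, vdw = NA_real_,
        stringsAsFactors = FALSE))
      x <- rbind(x, coordsList[[i]] + c(0.1, 0, 0))
    }
    residuesL[[i]] <- list(name = "GLY", chainId = LETTERS[i], seqNumber = i,
                           atoms = base + seq_len(perRes),
                           backbone = base + 1L, sidechain = integer(0),
                           donors = NULL, acceptors = integer(0),
                           rings = list(), methyls = integer(0))
    xyz <- rbind(xyz, x)
  }
  top <- new("Topology", atoms = atoms, residues = residuesL,
             chains = data.frame(id = LETTERS[seq_len(nC)], kind = "peptide",
                                 stringsAsFactors = FALSE))
  new("Trajectory", topology = top, coords = list(xyz),
      box = list(box), time = 0)
}

# donor-hydrogen-acceptor toy: residue 1 carries the D-H donor, residue 2
# the acceptor; arbitrary coordinates in nm.
hbondToy <- function(D, H, A, box = NULL) {
  atoms <- data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    resIndex = c(1L, 1L, 2L), isHydrogen = c(FALSE, TRUE, FALSE),
    mass = c(14.007, 1.008, 15.999), vdw = c(0.155, NA, 0.152),
    stringsAsFactors = FALSE)
  res1 <- list(name = "GLY", chainId = "A", seqNumber = 1L, atoms = 1:2,
               backbone = 1L, sidechain = integer(0),
               donors = matrix(c(1L, 2L), 1), acceptors = integer(0),
               rings = list(), methyls = integer(0))
  res2 <- list(name = "GLY", chainId = "B", seqNumber = 1L, atoms = 3L,
               backbone = 3L, sidechain = integer(0), donors = NULL,
               acceptors = 3L, rings = list(), methyls = integer(0))
  top <- new("Topology", atoms = atoms, residues = list(res1, res2),
             chains = data.frame(id = c("A", "B"), kind = "peptide",
                                 stringsAsFactors = FALSE))
  new("Trajectory", topology = top, coords = list(rbind(D, H, A)),
      box = list(box), time = 0)
}

# regular planar hexagon of circumradius r in the z = z0 plane
hexagonCoords <- function(r = 0.139, z0 = 0, center = c(0, 0, 0)) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), center[3] + z0)
}

# rigid motion helpers
randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

applyRigidMotion <- function(traj, R, t) {
  out <- traj
  out@coords <- lapply(traj@coords, function(x)
    sweep(x %*% t(R), 2, t, "+"))
  out
}

# reference DSSP codes via python/mdtraj on a written PDB; returns a list
# of per-frame code vectors restricted to standard amino-acid residues
mdtrajDssp <- function(traj) {
  pdb <- tempfile(fileext = ".pdb")
  writeMultiModelPDB(traj, pdb)
  out <- tempfile(fileext = ".txt")
  script <- sprintf(
    "import mdtraj as md\nt = md.load('%s')\nd = md.compute_dssp(t, simplified=False)\nwith open('%s','w') as f:\n    for row in d:\n        f.write(''.join('%%s' %% c for c in row) + '\\n')",
    pdb, out)
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) stop("mdtraj DSSP oracle failed")
  lines <- readLines(out)
  lapply(lines, function(ln) {
    # mdtraj writes 'NA' for non-protein residues (the caps); drop those
    codes <- strsplit(gsub("NA", "", ln), "")[[1]]
    codes[codes == " "] <- "C"
    codes
  })
}
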