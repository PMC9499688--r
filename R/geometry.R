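#' Minimum-image distance between two points
#'
#' Euclidean distance, optionally under orthorhombic periodic boundary
#' conditions. With a box the separation vector is wrapped into the
#' minimum image, which for an orthorhombic cell equals the minimum over
#' the 27 neighbouring image translations.
#'
#' @param a,b numeric(3) positions in nm.
#' @param box optional numeric(3) box edge lengths in nm.
#' @return distance in nm.
#' @examples
#' minImageDistance(c(0, 0, 0), c(3, 4, 0))               # 5
#' minImageDistance(c(0.1, 0, 0), c(4.9, 0, 0), c(5, 5, 5)) # 0.2
#' @export
minImageDistance <- function(a, b, box = NULL) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("minImageDistance: non-finite input coordinates")
  d <- b - a
  if (!is.null(box)) {
    if (any(!is.finite(box)) || any(box <= 0))
      stop("minImageDistance: box edges must be positive and finite")
    d <- d - box * round(d / box)
  }
  sqrt(sum(d * d))
}

# Wrap a matrix of displacement vectors into the minimum image (orthorhombic).
wrapDisplacements <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping \code{mobile} onto
#' \code{reference}, with the reflection excluded by a determinant
#' correction on the SVD. The fitted coordinates are
#' \code{mobile \%*\% t(rotation) + translation} (rows are points).
#'
#' @param reference,mobile M x 3 coordinate matrices in nm (M >= 3,
#'   non-collinear).
#' @param weights optional positive per-point weights.
#' @return a list with elements \code{rotation} (3 x 3 proper rotation),
#'   \code{translation} (numeric(3), nm) and \code{rmsd} (post-fit
#'   weighted RMSD, nm).
#' @export
kabschSuperpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!identical(dim(reference), dim(mobile)) || ncol(reference) != 3)
    stop("kabschSuperpose: point sets must be equal-sized M x 3 matrices")
  m <- nrow(reference)
  if (m < 3) stop("kabschSuperpose: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights <= 0))
    stop("kabschSuperpose: weights must be positive, one per point")
  w <- weights / sum(weights)
  comR <- colSums(reference * w)
  comM <- colSums(mobile * w)
  X <- sweep(mobile, 2, comM)     # mobile, centred
  Y <- sweep(reference, 2, comR)  # reference, centred
  sX <- svd(X)
  if (sX$d[2] < 1e-10 * max(1, sX$d[1]))
    stop("kabschSuperpose: degenerate (collinear) point set")
  H <- t(X * w) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)       # x' = R x for column vectors
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(comR - R %*% comM), rmsd = rmsd)
}

# RMSD between two conformations of the same point set after Kabsch fitting.
fittedRmsd <- function(reference, mobile) {
  kabschSuperpose(reference, mobile)$rmsd
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}.
#'
#' @param coords N x 3 coordinates in nm.
#' @param masses per-atom masses in amu; equal weighting when omitted.
#' @return radius of gyration in nm.
#' @export
radiusOfGyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1) stop("radiusOfGyration: need at least one atom")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n || any(masses <= 0))
    stop("radiusOfGyration: masses must be positive, one per atom")
  w <- masses / sum(masses)
  com <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, com)^2)))
}

#' Peptide end-to-end distance
#'
#' Distance between the C-alpha atoms of the first and last amino-acid
#' residues of a chain (terminal caps excluded), per frame.
#'
#' @param traj a [Trajectory-class].
#' @param chainId chain identifier; defaults to the first peptide chain.
#' @param frames frame indices (default all).
#' @return numeric vector of distances in nm, one per requested frame.
#' @export
endToEndDistance <- function(traj, chainId = NULL, frames = seq_len(nFrames(traj))) {
  top <- traj@topology
  if (is.null(chainId)) {
    pep <- top@chains$id[top@chains$kind == "peptide"]
    if (!length(pep)) stop("endToEndDistance: no peptide chains")
    chainId <- pep[1]
  }
  ri <- which(vapply(top@residues, function(r)
    r$chainId == chainId && !isCapName(r$name), TRUE))
  if (length(ri) < 2) stop("endToEndDistance: chain needs at least 2 amino-acid residues")
  caOf <- function(i) {
    r <- top@residues[[i]]
    ca <- r$atoms[top@atoms$name[r$atoms] == "CA"]
    if (!length(ca))
      stop(sprintf("endToEndDistance: residue %s%d has no CA atom",
                   r$name, r$seqNumber))
    ca[1]
  }
  a <- caOf(ri[1]); b <- caOf(ri[length(ri)])
  vapply(frames, function(f) {
    x <- traj@coords[[f]]
    sqrt(sum((x[a, ] - x[b, ])^2))
  }, 0)
}

isCapName <- function(name) name %in% c("ACE", "NH2", "NME")

#' Centroid, plane normal and planarity of a ring
#'
#' The normal is the least-squares plane normal (smallest principal
#' direction of the centred coordinates), sign-canonicalised to a
#' non-negative z component (ties resolved towards non-negative y, then x)
#' so stored normals are reproducible.
#'
#' @param ringAtoms matrix (>= 5 rows) of ring-atom coordinates in nm.
#' @return list with \code{centroid} (nm), \code{normal} (unit vector) and
#'   \code{planarityRmsd} (RMS out-of-plane deviation, nm).
#' @export
ringGeometry <- function(ringAtoms) {
  x <- as.matrix(ringAtoms)
  if (nrow(x) < 5) stop("ringGeometry: need at least 5 ring atoms")
  centroid <- colMeans(x)
  xc <- sweep(x, 2, centroid)
  s <- svd(xc)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-30))
    stop("ringGeometry: collinear ring atoms")
  n <- s$v[, 3]
  if (n[3] < 0 || (n[3] == 0 && (n[2] < 0 || (n[2] == 0 && n[1] < 0)))) n <- -n
  dev <- xc %*% n
  list(centroid = centroid, normal = as.numeric(n),
       planarityRmsd = sqrt(mean(dev^2)))
}

#' Angle between two ring planes
#'
#' \eqn{\arccos(|n_a \cdot n_b|)} in degrees, folded into [0, 90] so that
#' antiparallel normals are equivalent.
#'
#' @param a,b ring geometries from [ringGeometry()], or unit normals.
#' @return angle in degrees.
#' @export
interplaneAngle <- function(a, b) {
  na <- if (is.list(a)) a$normal else a
  nb <- if (is.list(b)) b$normal else b
  d <- abs(sum(na * nb)) / sqrt(sum(na^2) * sum(nb^2))
  acos(min(1, max(-1, d))) * 180 / pi
}

#' C-alpha RMSD of every frame to a reference frame
#'
#' Each frame is Kabsch-superposed onto the reference on the selected atom
#' set before the RMSD is evaluated, so rigid diffusion does not register
#' as conformational change.
#'
#' @param traj a [Trajectory-class].
#' @param selection atom indices (default: all peptide C-alpha atoms,
#'   jointly over all chains).
#' @param reference reference frame index (default 1, the initial
#'   structure).
#' @return numeric vector of RMSDs in nm, one per frame.
#' @export
rmsdToReference <- function(traj, selection = NULL, reference = 1L) {
  if (is.null(selection)) selection <- atomSelect(traj@topology, "peptide and name CA")
  ref <- traj@coords[[reference]][selection, , drop = FALSE]
  vapply(seq_len(nFrames(traj)), function(f)
    fittedRmsd(ref, traj@coords[[f]][selection, , drop = FALSE]), 0)
}

#' Pairwise post-fit RMSD matrix over frames
#'
#' @inheritParams rmsdToReference
#' @return symmetric nFrames x nFrames matrix in nm.
#' @export
pairwiseRmsd <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- atomSelect(traj@topology, "peptide and name CA")
  n <- nFrames(traj)
  xs <- lapply(seq_len(n), function(f) {
    x <- traj@coords[[f]][selection, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- centredRmsd(xs[[i]], xs[[j]])
    }
  }
  m
}

# RMSD after optimal rotation for two already-centred point sets.
centredRmsd <- function(X, Y) {
  s <- svd(t(Y) %*% X)
  d <- sign(det(s$v %*% t(s$u)))
  e2 <- (sum(X^2) + sum(Y^2) - 2 * sum(s$d * c(1, 1, d))) / nrow(X)
  sqrt(max(0, e2))
}

# NeRF internal-coordinate placement: position of atom D bonded to C with
# bond length |CD|, angle B-C-D and dihedral A-B-C-D (degrees, nm, IUPAC
# sign convention: dihedralAngle(a, b, c, placeAtom(a, b, c, ...)) == dihedral).
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracmaCross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("placeAtom: reference atoms are collinear")
  n <- n / nn
  m <- pracmaCross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracmaCross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Dihedral angle a-b-c-d in degrees, signed (IUPAC convention, matching
# the major trajectory toolkits).
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracmaCross(b1, b2); n2 <- pracmaCross(b2, b3)
  m1 <- pracmaCross(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rotation matrix about a unit axis by an angle in degrees (Rodrigues).
rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
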