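# Ensemble statistics: 1D probability densities, 2D potentials of mean
# force (-RT ln H), Daura (gromos) conformational clustering, cluster
# projection, and Jensen-Shannon convergence diagnostics.

GAS_CONSTANT_KCAL <- 0.0019872  # kcal / (mol K)

#' Normalised 1D probability density (histogram)
#'
#' Bin count defaults to the Freedman--Diaconis rule with a fallback to 50
#' bins; zero-variance input collapses to a single point-mass bin.
#'
#' @param samples numeric vector of observations.
#' @param binWidth optional fixed bin width (same units as the samples).
#' @param nBins optional fixed bin count (overrides the automatic rule).
#' @return list with \code{breaks}, \code{mids}, \code{density} (so that
#'   \code{sum(density * diff(breaks)) == 1}) and \code{n}.
#' @export
pdf1d <- function(samples, binWidth = NULL, nBins = NULL) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("pdf1d: need at least one finite sample")
  rng <- range(samples)
  if (rng[1] == rng[2]) {
    w <- if (!is.null(binWidth)) binWidth else max(abs(rng[1]) * 1e-3, 1e-6)
    breaks <- c(rng[1] - w / 2, rng[1] + w / 2)
    return(list(breaks = breaks, mids = rng[1], density = 1 / w,
                n = length(samples)))
  }
  if (is.null(binWidth)) {
    if (is.null(nBins)) {
      h <- 2 * stats::IQR(samples) / length(samples)^(1 / 3)
      nBins <- if (h > 0) max(1L, ceiling(diff(rng) / h)) else 50L
      nBins <- min(nBins, 10000L)
    }
    binWidth <- diff(rng) / nBins
  }
  breaks <- seq(rng[1], rng[2] + binWidth * 1e-8, by = binWidth)
  if (breaks[length(breaks)] < rng[2]) breaks <- c(breaks, rng[2] + binWidth)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, density = h$density,
       n = length(samples))
}

#' Two-dimensional potential of mean force
#'
#' \eqn{F(x, y) = -RT \ln H(x, y)} with \eqn{H} the normalised 2D
#' histogram of the paired samples, shifted so the global minimum over
#' populated bins is zero. Empty bins are undefined (masked), never
#' zero-filled.
#'
#' @param xSamples,ySamples paired observations (e.g. SASA in nm^2 and
#'   radius of gyration in nm).
#' @param temperature temperature in K (default 310, the analysis
#'   temperature of the replica ensemble).
#' @param bins integer(2) bin counts (default 50 x 50); the sampled range
#'   is padded by half a bin on each side.
#' @param xEdges,yEdges optional explicit bin edges.
#' @return a [PMFSurface-class].
#' @export
pmf2d <- function(xSamples, ySamples, temperature = 310, bins = c(50, 50),
                  xEdges = NULL, yEdges = NULL) {
  stopifnot(length(xSamples) == length(ySamples), temperature > 0)
  ok <- is.finite(xSamples) & is.finite(ySamples)
  x <- xSamples[ok]; y <- ySamples[ok]
  if (!length(x)) stop("pmf2d: no finite sample pairs")
  edgesFor <- function(v, nb) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    w <- diff(r) / nb
    seq(r[1] - w / 2, r[2] + w / 2, length.out = nb + 2L)
  }
  if (is.null(xEdges)) xEdges <- edgesFor(x, bins[1] - 1L)
  if (is.null(yEdges)) yEdges <- edgesFor(y, bins[2] - 1L)
  xi <- findInterval(x, xEdges, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, yEdges, rightmost.closed = TRUE, all.inside = TRUE)
  nx <- length(xEdges) - 1L; ny <- length(yEdges) - 1L
  H <- matrix(0, nx, ny)
  for (k in seq_along(xi)) H[xi[k], yi[k]] <- H[xi[k], yi[k]] + 1
  H <- H / sum(H)
  RT <- GAS_CONSTANT_KCAL * temperature
  FE <- matrix(NA_real_, nx, ny)
  defined <- H > 0
  FE[defined] <- -RT * log(H[defined])
  FE[defined] <- FE[defined] - min(FE[defined])
  new("PMFSurface", xEdges = xEdges, yEdges = yEdges, freeEnergy = FE,
      definedMask = defined, temperature = temperature, RT = RT)
}

#' Daura (gromos) conformational clustering
#'
#' Greedy medoid clustering on the pairwise post-fit C-alpha RMSD matrix:
#' the structure with the largest neighbour count (neighbours = frames
#' within the cutoff, self included) becomes a cluster medoid, its
#' neighbours are removed, and the procedure repeats until no frames
#' remain. Neighbour-count ties break to the lowest frame index.
#'
#' @param traj a [Trajectory-class].
#' @param selection atom indices for the RMSD (default all peptide
#'   C-alpha atoms, all chains jointly in fixed chain order).
#' @param cutoff RMSD cutoff in nm (default 0.45).
#' @param rmsdMatrix optional precomputed [pairwiseRmsd()] matrix.
#' @return a [ClusterResult-class].
#' @export
dauraCluster <- function(traj, selection = NULL, cutoff = 0.45,
                         rmsdMatrix = NULL) {
  if (is.null(rmsdMatrix)) rmsdMatrix <- pairwiseRmsd(traj, selection)
  n <- nrow(rmsdMatrix)
  within <- rmsdMatrix <= cutoff
  alive <- rep(TRUE, n)
  medoid <- integer(0); members <- list()
  while (any(alive)) {
    counts <- colSums(within[alive, , drop = FALSE])
    counts[!alive] <- -1L
    m <- which.max(counts)          # which.max takes the lowest index on ties
    grp <- which(alive & within[, m])
    medoid <- c(medoid, m)
    members[[length(members) + 1L]] <- grp
    alive[grp] <- FALSE
  }
  ord <- order(-vapply(members, length, 1L), medoid)
  new("ClusterResult", medoids = as.integer(medoid[ord]),
      members = members[ord], cutoff = cutoff)
}

#' Project top clusters onto a free-energy surface
#'
#' Returns, for the k most populated clusters, the medoid's reaction
#' coordinates and the cluster occupancy fraction.
#'
#' @param clusters a [ClusterResult-class].
#' @param xSamples,ySamples per-frame reaction coordinates aligned with
#'   the frame indices used for clustering.
#' @param k number of clusters to report (default 10; all if fewer).
#' @return data.frame with columns \code{cluster}, \code{medoidFrame},
#'   \code{x}, \code{y}, \code{fraction}.
#' @export
projectClusters <- function(clusters, xSamples, ySamples, k = 10L) {
  sizes <- clusterSizes(clusters)
  k <- min(k, length(sizes))
  total <- sum(sizes)
  idx <- seq_len(k)
  med <- clusters@medoids[idx]
  data.frame(cluster = idx, medoidFrame = med, x = xSamples[med],
             y = ySamples[med], fraction = sizes[idx] / total)
}

#' Jensen--Shannon divergence (base 2)
#'
#' Symmetric, bounded by 1 bit, zero iff the distributions coincide on
#' the shared support.
#'
#' @param p,q probability vectors on a shared binning (renormalised).
#' @return divergence in bits.
#' @export
jensenShannonDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Sampling-convergence diagnostic over two trajectory windows
#'
#' Compares three observables between two frame windows: the
#' secondary-structure category distribution, the PDF of the peptide
#' end-to-end distance, and the PDF of the per-frame inter-peptide
#' main-chain hydrogen-bond count, each on a shared binning. The windows
#' are declared converged when every Jensen--Shannon divergence is below
#' the threshold.
#'
#' @param traj a [Trajectory-class].
#' @param windowA,windowB integer frame-index vectors (each >= 10
#'   frames) or length-2 ranges \code{c(first, last)}.
#' @param threshold divergence threshold in bits (default 0.05).
#' @param nDistanceBins shared bin count for the end-to-end PDF.
#' @return list with \code{divergences} (named numeric), \code{threshold}
#'   and \code{pass}.
#' @export
convergenceCheck <- function(traj, windowA, windowB, threshold = 0.05,
                             nDistanceBins = 20L) {
  expand <- function(w) {
    if (length(w) == 2 && w[2] > w[1] + 1) w <- seq.int(w[1], w[2])
    w <- as.integer(w)
    if (any(w < 1 | w > nFrames(traj)))
      stop("convergenceCheck: window outside the trajectory")
    if (length(w) < 10) stop("convergenceCheck: windows need at least 10 frames")
    w
  }
  wa <- expand(windowA); wb <- expand(windowB)
  ss <- assignSecondaryStructure(traj)
  cats <- ssCategories(ss)
  lev <- ssCategoryNames()
  ssDist <- function(w) {
    tab <- table(factor(cats[w, , drop = FALSE], levels = lev))
    as.numeric(tab)
  }
  pep <- traj@topology@chains$id[traj@topology@chains$kind == "peptide"]
  e2e <- lapply(pep, function(cid) endToEndDistance(traj, cid))
  e2eOf <- function(w) unlist(lapply(e2e, `[`, w))
  allE <- c(e2eOf(wa), e2eOf(wb))
  brk <- seq(min(allE), max(allE) + 1e-9, length.out = nDistanceBins + 1L)
  e2eDist <- function(w)
    graphics::hist(e2eOf(w), breaks = brk, plot = FALSE)$counts
  hb <- detectHBonds(traj, scope = "peptide")
  chainOf <- vapply(traj@topology@residues, function(r) r$chainId, "")
  sel <- hb$class == "MC-MC" & chainOf[hb$donorRes] != chainOf[hb$acceptorRes]
  perFrame <- tabulate(hb$frame[sel], nbins = nFrames(traj))
  maxC <- max(perFrame)
  hbDist <- function(w) tabulate(perFrame[w] + 1L, nbins = maxC + 1L)
  div <- c(
    secondaryStructure = jensenShannonDivergence(ssDist(wa), ssDist(wb)),
    endToEnd = jensenShannonDivergence(e2eDist(wa), e2eDist(wb)),
    hbondCount = jensenShannonDivergence(hbDist(wa), hbDist(wb)))
  list(divergences = div, threshold = threshold, pass = all(div < threshold))
}
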