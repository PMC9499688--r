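#' @import methods
NULL

#' Molecular topology
#'
#' A \code{Topology} describes the chemical identity of a system: an ordered
#' atom table, a list of residue records carrying role annotations
#' (backbone/side-chain partition, hydrogen-bond donors and acceptors,
#' aromatic rings, methyl carbons), and a chain table tagging each chain as
#' \code{peptide} or \code{ligand}. All coordinates elsewhere in the package
#' are interpreted against a \code{Topology}.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resIndex} (1-based), \code{isHydrogen},
#'   \code{mass} (amu) and \code{vdw} (nm; \code{NA} for hydrogens).
#' @slot residues list of residue records; each record is a list with
#'   elements \code{name}, \code{chainId}, \code{seqNumber}, \code{atoms},
#'   \code{backbone}, \code{sidechain}, \code{donors} (two-column integer
#'   matrix: donor heavy atom, bonded hydrogen), \code{acceptors},
#'   \code{rings} (list of integer vectors) and \code{methyls}. All indices
#'   are rows of \code{atoms}.
#' @slot chains data.frame with columns \code{id} and \code{kind}
#'   (\code{"peptide"} or \code{"ligand"}).
#'
#' @seealso [readMultiModelPDB()], [buildPeptide()]
#' @export
setClass("Topology",
  representation(atoms = "data.frame", residues = "list", chains = "data.frame"))

setValidity("Topology", function(object) {
  msgs <- character()
  at <- object@atoms
  need <- c("serial", "name", "element", "resIndex", "isHydrogen", "mass", "vdw")
  if (!all(need %in% names(at)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (any(!nzchar(at$element))) msgs <- c(msgs, "every atom needs a non-empty element")
  if (any(at$mass <= 0)) msgs <- c(msgs, "atom masses must be positive")
  if (any(!at$isHydrogen & !(at$vdw > 0), na.rm = FALSE))
    msgs <- c(msgs, "non-hydrogen atoms must carry a positive vdW radius")
  if (nrow(at) && (any(at$resIndex < 1) || any(at$resIndex > length(object@residues))))
    msgs <- c(msgs, "atom resIndex out of range")
  seen <- integer(0)
  for (i in seq_along(object@residues)) {
    r <- object@residues[[i]]
    heavy <- r$atoms[!at$isHydrogen[r$atoms]]
    if (!setequal(c(r$backbone, r$sidechain), heavy) ||
        length(intersect(r$backbone, r$sidechain)))
      msgs <- c(msgs, sprintf("residue %d: backbone/sidechain must partition its heavy atoms", i))
    if (!all(r$chainId %in% object@chains$id))
      msgs <- c(msgs, sprintf("residue %d: unknown chain id '%s'", i, r$chainId))
    if (length(r$rings) && any(vapply(r$rings, length, 1L) < 5))
      msgs <- c(msgs, sprintf("residue %d: rings need at least 5 atoms", i))
    seen <- c(seen, r$atoms)
  }
  if (length(object@residues) && !setequal(seen, seq_len(nrow(at))))
    msgs <- c(msgs, "residue atom lists must cover the atom table exactly")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Coordinate trajectory
#'
#' An ordered list of frames (coordinate snapshots in nm, with an optional
#' orthorhombic box) over a shared [Topology-class].
#'
#' @slot topology the [Topology-class].
#' @slot coords list of N x 3 numeric matrices, one per frame, in nm.
#' @slot box list, one entry per frame: numeric(3) edge lengths in nm or
#'   \code{NULL}.
#' @slot time numeric frame times (ps or frame index).
#' @export
setClass("Trajectory",
  representation(topology = "Topology", coords = "list", box = "list",
                 time = "numeric"))

setValidity("Trajectory", function(object) {
  if (!length(object@coords)) return("a Trajectory needs at least one frame")
  na <- nrow(object@topology@atoms)
  for (i in seq_along(object@coords)) {
    x <- object@coords[[i]]
    if (!is.matrix(x) || ncol(x) != 3 || nrow(x) != na)
      return(sprintf("frame %d: coordinates must be a %d x 3 matrix", i, na))
    if (!all(is.finite(x))) return(sprintf("frame %d: non-finite coordinates", i))
    b <- object@box[[i]]
    if (!is.null(b) && (length(b) != 3 || any(!is.finite(b)) || any(b <= 0)))
      return(sprintf("frame %d: box must be three positive edge lengths", i))
  }
  if (length(object@box) != length(object@coords)) return("box list length mismatch")
  if (length(object@time) != length(object@coords)) return("time vector length mismatch")
  TRUE
})

#' Per-frame, per-residue secondary structure
#'
#' Eight-state Kabsch--Sander codes (\code{H,G,I,E,B,T,S,C}) for every
#' peptide residue in every frame, together with the six-category mapping
#' used for population summaries (helix, beta-sheet, beta-bridge, turn,
#' bend, coil).
#'
#' @slot codes character matrix, frames x residues, entries in
#'   \code{c("H","G","I","E","B","T","S","C")}.
#' @slot residueIndex integer vector mapping columns to topology residues.
#' @slot labels residue labels, e.g. \code{"S20"}.
#' @export
setClass("SecondaryStructure",
  representation(codes = "matrix", residueIndex = "integer", labels = "character"))

setValidity("SecondaryStructure", function(object) {
  ok <- object@codes %in% c("H", "G", "I", "E", "B", "T", "S", "C")
  if (!all(ok)) return("codes must be one of H,G,I,E,B,T,S,C")
  if (ncol(object@codes) != length(object@residueIndex)) return("residueIndex length mismatch")
  if (ncol(object@codes) != length(object@labels)) return("labels length mismatch")
  TRUE
})

#' Inter-peptide residue contact probability map
#'
#' @slot labels residue-position labels (e.g. \code{S20}..\code{S29}).
#' @slot probabilities symmetric L x L matrix of contact probabilities.
#' @slot contactClass \code{"MC-MC"} or \code{"SC-SC"}.
#' @slot nFrames,nChainPairs integers recording the averaging denominator.
#' @export
setClass("ContactMap",
  representation(labels = "character", probabilities = "matrix",
                 contactClass = "character", nFrames = "integer",
                 nChainPairs = "integer"))

setValidity("ContactMap", function(object) {
  p <- object@probabilities
  if (nrow(p) != ncol(p) || nrow(p) != length(object@labels))
    return("probability matrix must be square and match labels")
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) return("probabilities must lie in [0,1]")
  if (max(abs(p - t(p))) > 1e-12) return("probability matrix must be symmetric")
  TRUE
})

#' Two-dimensional potential of mean force
#'
#' Binned free-energy surface \eqn{F(x,y) = -RT \ln H(x,y)} in kcal/mol,
#' shifted so the global minimum over populated bins is zero; empty bins are
#' masked as undefined rather than zero-filled.
#'
#' @slot xEdges,yEdges bin edges of the two reaction coordinates.
#' @slot freeEnergy numeric matrix (nx x ny), kcal/mol; \code{NA} where
#'   undefined.
#' @slot definedMask logical matrix, \code{TRUE} where the bin is populated.
#' @slot temperature temperature in K.
#' @slot RT thermal energy in kcal/mol (gas constant 0.0019872
#'   kcal/(mol K) times temperature).
#' @export
setClass("PMFSurface",
  representation(xEdges = "numeric", yEdges = "numeric", freeEnergy = "matrix",
                 definedMask = "matrix", temperature = "numeric", RT = "numeric"))

setValidity("PMFSurface", function(object) {
  if (!identical(dim(object@freeEnergy), dim(object@definedMask)))
    return("freeEnergy and definedMask must have identical dimensions")
  if (nrow(object@freeEnergy) != length(object@xEdges) - 1 ||
      ncol(object@freeEnergy) != length(object@yEdges) - 1)
    return("grid dimensions must match bin edges")
  if (any(object@definedMask & is.na(object@freeEnergy)))
    return("defined bins cannot be NA")
  if (any(object@definedMask)) {
    m <- min(object@freeEnergy[object@definedMask])
    if (abs(m) > 1e-9) return("minimum over defined bins must be zero")
  }
  if (abs(object@RT - 0.0019872 * object@temperature) > 1e-12)
    return("RT must equal 0.0019872 * temperature")
  TRUE
})

#' Daura (gromos) clustering result
#'
#' Greedy medoid clusters on the pairwise post-fit C-alpha RMSD matrix:
#' repeatedly extract the frame with the largest neighbour count within the
#' cutoff. Clusters are ordered by size (ties by medoid frame index).
#'
#' @slot medoids integer frame indices of cluster centres.
#' @slot members list of integer vectors partitioning all frames.
#' @slot cutoff RMSD cutoff in nm.
#' @export
setClass("ClusterResult",
  representation(medoids = "integer", members = "list", cutoff = "numeric"))

setValidity("ClusterResult", function(object) {
  if (length(object@medoids) != length(object@members))
    return("one medoid per cluster required")
  sizes <- vapply(object@members, length, 1L)
  if (is.unsorted(rev(sizes))) return("cluster sizes must be non-increasing")
  all_members <- unlist(object@members)
  if (anyDuplicated(all_members)) return("clusters must be disjoint")
  for (k in seq_along(object@medoids))
    if (!(object@medoids[k] %in% object@members[[k]]))
      return("each medoid must belong to its own cluster")
  TRUE
})
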