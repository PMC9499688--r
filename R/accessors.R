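#' @rdname Topology-class
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname Trajectory-class
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @rdname Topology-class
setMethod("nResidues", "Topology", function(x) length(x@residues))

#' @rdname Trajectory-class
setMethod("nResidues", "Trajectory", function(x) length(x@topology@residues))

#' @rdname Trajectory-class
setMethod("nFrames", "Trajectory", function(x) length(x@coords))

#' @rdname Topology-class
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname Trajectory-class
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname Topology-class
setMethod("residues", "Topology", function(x) x@residues)

#' @rdname Trajectory-class
setMethod("residues", "Trajectory", function(x) x@topology@residues)

#' @rdname Topology-class
setMethod("chains", "Topology", function(x) x@chains)

#' @rdname Trajectory-class
setMethod("chains", "Trajectory", function(x) x@topology@chains)

#' @rdname Trajectory-class
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname getFrame
setMethod("getFrame", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= length(x@coords))
  list(coords = x@coords[[i]], box = x@box[[i]], time = x@time[i])
})

#' @rdname getFrame
setMethod("frameCoords", "Trajectory", function(x, i) x@coords[[i]])

#' @rdname SecondaryStructure-class
setMethod("ssCodes", "SecondaryStructure", function(x) x@codes)

#' @rdname SecondaryStructure-class
setMethod("nFrames", "SecondaryStructure", function(x) nrow(x@codes))

#' Map eight-state codes to the six reported categories
#'
#' \code{H}, \code{G} and \code{I} pool into \code{helix}; \code{E} is
#' \code{beta-sheet}; \code{B} is \code{beta-bridge}; \code{T} is
#' \code{turn}; \code{S} is \code{bend}; everything else is \code{coil}.
#'
#' @param x a [SecondaryStructure-class]
#' @return a character matrix of categories, frames x residues
#' @rdname SecondaryStructure-class
setMethod("ssCategories", "SecondaryStructure", function(x) {
  m <- ssCategoryMap()[x@codes]
  dim(m) <- dim(x@codes)
  dimnames(m) <- dimnames(x@codes)
  m
})

ssCategoryNames <- function() {
  c("helix", "beta-sheet", "beta-bridge", "turn", "bend", "coil")
}

ssCategoryMap <- function() {
  c(H = "helix", G = "helix", I = "helix", E = "beta-sheet",
    B = "beta-bridge", T = "turn", S = "bend", C = "coil")
}

#' @rdname ClusterResult-class
setMethod("clusterSizes", "ClusterResult", function(x) vapply(x@members, length, 1L))

#' @rdname ClusterResult-class
setMethod("medoids", "ClusterResult", function(x) x@medoids)

#' @rdname ClusterResult-class
setMethod("clusterMembers", "ClusterResult", function(x) x@members)

#' @rdname ContactMap-class
setMethod("contactProbabilities", "ContactMap", function(x) x@probabilities)

#' @rdname PMFSurface-class
setMethod("freeEnergy", "PMFSurface", function(x) x@freeEnergy)

setMethod("show", "Topology", function(object) {
  kinds <- table(object@chains$kind)
  cat(sprintf("Topology: %d atoms, %d residues, %d chains (%s)\n",
              nrow(object@atoms), length(object@residues), nrow(object@chains),
              paste(sprintf("%d %s", as.integer(kinds), names(kinds)), collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  hasBox <- !vapply(object@box, is.null, TRUE)
  cat(sprintf("Trajectory: %d frames x %d atoms (%s)\n",
              length(object@coords), nrow(object@topology@atoms),
              if (all(hasBox)) "periodic box" else "no box"))
  show(object@topology)
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d frames x %d residues\n",
              nrow(object@codes), ncol(object@codes)))
  tab <- prop.table(table(factor(object@codes,
                                 levels = c("H", "G", "I", "E", "B", "T", "S", "C"))))
  cat("  code fractions:",
      paste(sprintf("%s=%.3f", names(tab), as.numeric(tab)), collapse = " "), "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%s): %d x %d residue positions, %d frames x %d chain pairs\n",
              object@contactClass, nrow(object@probabilities), ncol(object@probabilities),
              object@nFrames, object@nChainPairs))
  cat(sprintf("  max probability %.3f\n", max(object@probabilities)))
})

setMethod("show", "PMFSurface", function(object) {
  cat(sprintf("PMFSurface: %d x %d bins at %g K (RT = %.5f kcal/mol), %d defined bins\n",
              nrow(object@freeEnergy), ncol(object@freeEnergy),
              object@temperature, object@RT, sum(object@definedMask)))
})

setMethod("show", "ClusterResult", function(object) {
  sizes <- clusterSizes(object)
  cat(sprintf("ClusterResult: %d clusters over %d frames (cutoff %.3g nm)\n",
              length(sizes), sum(sizes), object@cutoff))
  k <- min(10L, length(sizes))
  cat("  top sizes:", paste(sizes[seq_len(k)], collapse = " "), "\n")
})
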