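#' @rdname Topology-class
#' @param object,x an object of the documented class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Topology-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Topology-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Topology-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname Topology-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname Trajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Extract one frame of a trajectory
#'
#' @param x a [Trajectory-class]
#' @param i frame index (1-based)
#' @return a list with elements \code{coords} (N x 3 matrix, nm),
#'   \code{box} (numeric(3) or \code{NULL}) and \code{time}.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("ssCodes", function(x) standardGeneric("ssCodes"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("ssCategories", function(x) standardGeneric("ssCategories"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname ClusterResult-class
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname ContactMap-class
#' @export
setGeneric("contactProbabilities", function(x) standardGeneric("contactProbabilities"))

#' @rdname PMFSurface-class
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
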