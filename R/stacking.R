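# Aromatic stacking geometry: ring-ring (pi-pi) centroid distance and
# interplane angle with closest-partner pairing, and methyl-to-ring CH-pi
# minimum distances.

#' Ring selections of a topology
#'
#' Convenience accessor for annotated aromatic rings: all rings of the
#' residues matched by a selection expression. Six-membered rings only
#' (e.g. the phenylalanine ring, the benzene ring of melatonin's indole)
#' unless \code{sixOnly = FALSE}.
#'
#' @param topology a [Topology-class].
#' @param expression an [atomSelect()] expression describing the residues
#'   (any residue with at least one selected atom is included).
#' @param sixOnly keep only six-membered rings.
#' @return list of integer atom-index vectors.
#' @export
ringSelection <- function(topology, expression, sixOnly = TRUE) {
  sel <- atomSelect(topology, expression)
  resIdx <- sort(unique(topology@atoms$resIndex[sel]))
  out <- list()
  for (ri in resIdx) {
    for (ring in topology@residues[[ri]]$rings) {
      if (sixOnly && length(ring) != 6) next
      out[[length(out) + 1L]] <- ring
    }
  }
  out
}

classifyStacking <- function(angle, parallelMax = 30, herringboneMin = 50) {
  ifelse(angle <= parallelMax, "parallel",
         ifelse(angle >= herringboneMin, "herringbone", "intermediate"))
}

#' Closest-ring stacking events
#'
#' Per frame, each ring of \code{ringsA} is paired with the ring of
#' \code{ringsB} of minimum centroid distance; the centroid distance,
#' interplane angle (folded to [0, 90] degrees) and a classification
#' (parallel / intermediate / herringbone) are recorded. Rings sharing
#' atoms are never paired with themselves.
#'
#' @param traj a [Trajectory-class].
#' @param ringsA,ringsB lists of ring atom-index vectors (see
#'   [ringSelection()]).
#' @param frames frame indices (default all).
#' @param parallelMax,herringboneMin classification thresholds in degrees
#'   (parallel below 30, herringbone above 50 by convention).
#' @return data.frame with columns \code{frame}, \code{ringA},
#'   \code{ringB}, \code{distance} (nm), \code{angle} (degrees),
#'   \code{classification}.
#' @export
stackingEvents <- function(traj, ringsA, ringsB, frames = seq_len(nFrames(traj)),
                           parallelMax = 30, herringboneMin = 50) {
  if (!length(ringsA) || !length(ringsB))
    stop("stackingEvents: both ring selections must be non-empty")
  out <- list()
  for (f in frames) {
    x <- traj@coords[[f]]
    geomA <- lapply(ringsA, function(r) ringGeometry(x[r, , drop = FALSE]))
    geomB <- lapply(ringsB, function(r) ringGeometry(x[r, , drop = FALSE]))
    cenB <- do.call(rbind, lapply(geomB, `[[`, "centroid"))
    for (a in seq_along(ringsA)) {
      dv <- sweep(cenB, 2, geomA[[a]]$centroid)
      d <- sqrt(rowSums(dv^2))
      same <- vapply(ringsB, function(r) length(intersect(r, ringsA[[a]])) > 0, TRUE)
      d[same] <- Inf
      if (all(!is.finite(d))) next
      b <- which.min(d)
      ang <- interplaneAngle(geomA[[a]], geomB[[b]])
      out[[length(out) + 1L]] <- data.frame(
        frame = f, ringA = a, ringB = b, distance = d[b], angle = ang,
        classification = classifyStacking(ang, parallelMax, herringboneMin),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), ringA = integer(0), ringB = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      classification = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Minimum methyl-to-ring (CH-pi) distance per frame
#'
#' Per frame, the minimum over the annotated methyl carbons of the
#' selected residues and the partner rings of the carbon-to-ring-centroid
#' distance (default), or of the minimum carbon-to-ring-atom distance
#' with \code{mode = "ringatoms"}.
#'
#' @param traj a [Trajectory-class].
#' @param methylExpression selection expression for the methyl-bearing
#'   residues (e.g. \code{"resname ILE"}).
#' @param rings list of ring atom-index vectors.
#' @param frames frame indices (default all).
#' @param mode \code{"centroid"} or \code{"ringatoms"}.
#' @return numeric vector of distances in nm, one per frame.
#' @export
chpiMinDistance <- function(traj, methylExpression, rings,
                            frames = seq_len(nFrames(traj)),
                            mode = c("centroid", "ringatoms")) {
  mode <- match.arg(mode)
  top <- traj@topology
  sel <- atomSelect(top, methylExpression)
  resIdx <- sort(unique(top@atoms$resIndex[sel]))
  methyls <- integer(0)
  for (ri in resIdx) {
    m <- top@residues[[ri]]$methyls
    if (!length(m)) {
      r <- top@residues[[ri]]
      stop(sprintf("chpiMinDistance: residue %s%d has no methyl annotation",
                   r$name, r$seqNumber))
    }
    methyls <- c(methyls, m)
  }
  if (!length(rings)) stop("chpiMinDistance: empty ring selection")
  vapply(frames, function(f) {
    x <- traj@coords[[f]]
    best <- Inf
    for (r in rings) {
      ref <- if (mode == "centroid") {
        matrix(ringGeometry(x[r, , drop = FALSE])$centroid, 1)
      } else x[r, , drop = FALSE]
      for (m in methyls) {
        d <- sqrt(min(rowSums(sweep(ref, 2, x[m, ])^2)))
        if (d < best) best <- d
      }
    }
    best
  }, 0)
}
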