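#' Number of atoms in an object
#' @param x a Topology, Conformation or Trajectory.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Conformation", function(x) nrow(x@coords))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1L])

#' Number of frames in a trajectory
#' @param x a Trajectory.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3L])

#' Atom table of an object's topology
#' @param x a Topology, Conformation or Trajectory.
#' @return data.frame with one row per atom.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "Topology", function(x) x@atoms)
#' @rdname atomData
#' @export
setMethod("atomData", "Conformation", function(x) x@topology@atoms)
#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' Topology accessor
#' @param x a Conformation or Trajectory.
#' @return the underlying \linkS4class{Topology}.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname topology
#' @export
setMethod("topology", "Conformation", function(x) x@topology)
#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' Coordinates accessor
#' @param x a Conformation (atoms x 3 matrix) or Trajectory
#'   (atoms x 3 x frames array), in nm.
#' @return numeric matrix or array.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Conformation", function(x) x@coords)
#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

#' Frame times accessor
#' @param x a Trajectory or ScoreSeries.
#' @return numeric vector of times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname frameTimes
#' @export
setMethod("frameTimes", "ScoreSeries", function(x) x@times)

#' Chain identifiers of a topology
#' @param x a Topology, Conformation or Trajectory.
#' @return character vector of chain ids in order of first appearance.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "Topology", function(x) unique(x@atoms$chain))
#' @rdname chainIds
#' @export
setMethod("chainIds", "Conformation", function(x) unique(x@topology@atoms$chain))
#' @rdname chainIds
#' @export
setMethod("chainIds", "Trajectory", function(x) unique(x@topology@atoms$chain))

#' Score values accessor
#' @param x a ScoreSeries.
#' @return numeric vector of per-frame scores in [0, 1].
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname scoreValues
#' @export
setMethod("scoreValues", "ScoreSeries", function(x) x@values)

#' Occupancy percentages accessor
#' @param x an OccupancyMap.
#' @return donor x acceptor matrix of percentages.
#' @export
setGeneric("occupancyPercent", function(x) standardGeneric("occupancyPercent"))

#' @rdname occupancyPercent
#' @export
setMethod("occupancyPercent", "OccupancyMap", function(x) x@percent)

#' Cluster assignments accessor
#' @param x a ClusterResult.
#' @return integer vector of per-frame cluster ids.
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname clusterIds
#' @export
setMethod("clusterIds", "ClusterResult", function(x) x@ids)

#' Cluster centers accessor
#' @param x a ClusterResult.
#' @return integer vector of center frame indices, in extraction order.
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname clusterCenters
#' @export
setMethod("clusterCenters", "ClusterResult", function(x) x@centers)

#' Cluster sizes accessor
#' @param x a ClusterResult.
#' @return integer vector of cluster sizes.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) x@sizes)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  ch <- unique(a$chain)
  cat(sprintf("Topology: %d atoms, %d chain(s) [%s], %d residue(s)/chain\n",
              nrow(a), length(ch), paste(ch, collapse = ","),
              max(a$resid[a$chain == ch[1L]])))
})

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d atoms, %d chain(s)\n",
              nrow(object@coords), length(unique(object@topology@atoms$chain))))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.1f..%.1f ps%s\n",
              d[3L], d[1L], object@times[1L], object@times[d[3L]],
              if (nrow(object@box) > 0L) ", periodic box" else ""))
})

setMethod("show", "SwitchingParams", function(object) {
  cat(sprintf("SwitchingParams: d0 = %g nm, n = %g, m = %g\n",
              object@d0, object@n, object@m))
})

setMethod("show", "OccupancyMap", function(object) {
  cat(sprintf("OccupancyMap (%s): %d x %d residues, %d frame(s) over %d run(s)\n",
              object@scope, nrow(object@percent), ncol(object@percent),
              object@nFrames, object@nRuns))
})

setMethod("show", "ScoreSeries", function(object) {
  cat(sprintf("ScoreSeries (%s): %d frames, mean %.1f%%\n",
              object@kind, length(object@values), 100 * mean(object@values)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d frames in %d cluster(s), cutoff %g nm\n",
              length(object@ids), length(object@centers), object@cutoff))
})
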