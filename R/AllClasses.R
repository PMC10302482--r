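#' @import methods
NULL

ATOM_ROLES <- c("N", "H", "CB", "CA", "C", "O", "other")

#' Topology of a (multi-)chain beta-peptide system
#'
#' Describes atoms grouped into 1-based residues grouped into chains, with the
#' backbone role of every atom. Roles follow the beta-amino acid backbone
#' (amide N, amide H, C-beta, C-alpha, carbonyl C, carbonyl O); everything
#' else, e.g. side-chain pseudo-atoms, is \code{"other"}. The hydrogen-bond
#' donor/acceptor registry used by the analytics is derived from the roles:
#' amide N--H pairs donate, carbonyl O atoms accept.
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{chain}, \code{resid} (1-based within chain), \code{resname},
#'   \code{role}.
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("name", "element", "chain", "resid", "resname", "role")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("topology has no atoms")
  if (!all(a$role %in% ATOM_ROLES))
    return("unknown backbone role")
  if (any(a$resid < 1L)) return("residue indices must be 1-based")
  ## at most one amide H and one carbonyl O per residue
  key <- paste(a$chain, a$resid)
  if (any(tapply(a$role == "H", key, sum) > 1L))
    return("more than one amide H in a residue")
  if (any(tapply(a$role == "O", key, sum) > 1L))
    return("more than one carbonyl O in a residue")
  TRUE
})

#' A single conformation: topology plus Cartesian coordinates in nm
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric matrix, atoms x 3, in nm.
#' @export
setClass("Conformation",
         representation(topology = "Topology", coords = "matrix"))

setValidity("Conformation", function(object) {
  if (nrow(object@coords) != nrow(object@topology@atoms))
    return("coordinate count does not match topology atom count")
  if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' An ordered set of frames sharing one topology
#'
#' Coordinates are stored as an atoms x 3 x frames array in nm; times are in
#' ps and strictly increasing. The optional orthorhombic box is a frames x 3
#' matrix of box edge lengths in nm (a 0-row matrix means open boundaries).
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric array, atoms x 3 x frames (nm).
#' @slot times numeric vector of frame times (ps).
#' @slot box frames x 3 matrix of box lengths (nm), or 0-row matrix.
#' @export
setClass("Trajectory",
         representation(topology = "Topology", coords = "array",
                        times = "numeric", box = "matrix"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    return("coords must be an atoms x 3 x frames array")
  if (d[1L] != nrow(object@topology@atoms))
    return("frame coordinate count does not match topology")
  if (d[3L] != length(object@times))
    return("times length does not match frame count")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (nrow(object@box) > 0L) {
    if (nrow(object@box) != d[3L] || ncol(object@box) != 3L)
      return("box must be frames x 3")
    if (any(object@box <= 0)) return("box lengths must be positive")
  }
  TRUE
})

#' Parameters of the hydrogen-bond switching function
#'
#' The continuous hydrogen-bond score is the rational switching function
#' \deqn{s(d) = \frac{1 - (d/d_0)^n}{1 - (d/d_0)^m}}
#' of the hydrogen--acceptor-oxygen distance \eqn{d}, continuously extended
#' with \eqn{s(d_0) = n/m}. The defaults (\eqn{d_0} = 0.25 nm, n = 6, m = 10)
#' place the 50\% crossing at 0.27 nm and the 10\% crossing at 0.44 nm, the
#' calibration used for beta-peptide backbone hydrogen bonds.
#'
#' @slot d0 reference distance in nm.
#' @slot n numerator exponent.
#' @slot m denominator exponent (> n).
#' @export
setClass("SwitchingParams",
         representation(d0 = "numeric", n = "numeric", m = "numeric"))

setValidity("SwitchingParams", function(object) {
  if (length(object@d0) != 1L || object@d0 <= 0) return("d0 must be > 0")
  if (object@n <= 0 || object@m <= object@n)
    return("exponents must satisfy 0 < n < m")
  TRUE
})

#' Geometric criteria for discrete hydrogen-bond detection
#'
#' A donor/hydrogen/acceptor triple is counted as hydrogen bonded when the
#' donor--acceptor heavy-atom distance is below \code{maxDonorAcceptor}, the
#' donor-hydrogen-acceptor angle exceeds \code{minAngle} and the hydrogen sits
#' within \code{maxDonorH} of its donor.
#'
#' @slot maxDonorAcceptor nm, default 0.3.
#' @slot minAngle degrees, default 150.
#' @slot maxDonorH nm, default 0.12.
#' @export
setClass("HBondCriteria",
         representation(maxDonorAcceptor = "numeric", minAngle = "numeric",
                        maxDonorH = "numeric"))

setValidity("HBondCriteria", function(object) {
  if (object@maxDonorAcceptor <= 0 || object@maxDonorH <= 0)
    return("distance cutoffs must be positive")
  if (object@minAngle <= 0 || object@minAngle > 180)
    return("angle cutoff must be in (0, 180]")
  TRUE
})

#' Residue-residue hydrogen-bond occupancy map
#'
#' Entry (i, j) is the percentage of pooled frames (over one or more runs) in
#' which at least one hydrogen bond links donor residue i to acceptor residue
#' j.
#'
#' @slot percent donor-residue x acceptor-residue matrix of percentages.
#' @slot nFrames total frames pooled.
#' @slot nRuns number of runs pooled.
#' @slot scope one of "intrachain", "interchain", "all".
#' @export
setClass("OccupancyMap",
         representation(percent = "matrix", nFrames = "integer",
                        nRuns = "integer", scope = "character"))

setValidity("OccupancyMap", function(object) {
  if (any(object@percent < 0 | object@percent > 100))
    return("occupancies must lie in [0, 100]")
  if (object@nFrames < 1L) return("no frames pooled")
  TRUE
})

#' Per-frame secondary-structure propensity scores
#'
#' @slot times frame times in ps.
#' @slot values scores in [0, 1] (multiply by 100 for percent).
#' @slot kind "helicity" or "hairpin".
#' @export
setClass("ScoreSeries",
         representation(times = "numeric", values = "numeric",
                        kind = "character"))

setValidity("ScoreSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values differ in length")
  if (any(object@values < -1e-9 | object@values > 1 + 1e-9))
    return("scores must lie in [0, 1]")
  TRUE
})

#' Result of Daura conformational clustering
#'
#' @slot ids integer cluster id per frame (1 = first extracted cluster).
#' @slot centers frame index of each cluster's center, in extraction order.
#' @slot sizes number of frames in each cluster.
#' @slot cutoff RMSD cutoff used (nm).
#' @export
setClass("ClusterResult",
         representation(ids = "integer", centers = "integer",
                        sizes = "integer", cutoff = "numeric"))

setValidity("ClusterResult", function(object) {
  k <- length(object@centers)
  if (length(object@sizes) != k) return("centers/sizes length mismatch")
  if (sum(object@sizes) != length(object@ids))
    return("cluster sizes must sum to the frame count")
  if (k > 0L && !all(object@ids[object@centers] == seq_len(k)))
    return("every center must belong to its own cluster")
  TRUE
})
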