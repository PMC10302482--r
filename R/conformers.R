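## Structural comparison: least-squares superposition RMSD, Daura
## conformational clustering, and cumulative cluster-count convergence.

#' Optimal superposition of two coordinate sets
#'
#' Least-squares rigid-body superposition (Kabsch algorithm via singular
#' value decomposition, restricted to proper rotations): finds the rotation R
#' and translation t minimizing the RMSD between `R mobile + t` and
#' `reference` over the selected atoms.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm) with equal atom
#'   counts, or Conformations.
#' @param selection optional integer atom indices used for the fit (default:
#'   all atoms).
#' @return list with elements `rmsd` (nm), `rotation` (3 x 3 proper rotation,
#'   det +1), `translation` (length-3, nm) and `degenerate` (TRUE when the
#'   selection is essentially collinear, in which case the optimum is not
#'   unique).
#' @export
#' @examples
#' conf <- presetConformation("helix314", 4)
#' superpose(coords(conf), coords(conf))$rmsd
superpose <- function(mobile, reference, selection = NULL) {
  if (is(mobile, "Conformation")) mobile <- mobile@coords
  if (is(reference, "Conformation")) reference <- reference@coords
  if (!is.null(selection)) {
    mobile <- mobile[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(mobile) != nrow(reference))
    stopf("selected atom counts differ (%d vs %d)", nrow(mobile),
          nrow(reference))
  if (nrow(mobile) < 3L)
    stopf("superposition needs at least 3 atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  ## degenerate (collinear) selections leave a rotation axis undetermined
  degenerate <- sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-30)
  fitted <- t(R %*% t(P))
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cr - R %*% cm),
       degenerate = degenerate)
}

#' Pairwise superposed RMSD between trajectory frames
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection integer atom indices used for the fit (default: all).
#' @return symmetric frames x frames matrix of minimal RMSDs (nm).
#' @export
pairwiseRMSD <- function(traj, selection = NULL) {
  nf <- nFrames(traj)
  sel <- selection %||% seq_len(nAtoms(traj))
  frames <- lapply(seq_len(nf), function(k)
    traj@coords[sel, , k, drop = FALSE][, , 1L])
  m <- matrix(0, nf, nf)
  if (nf < 2L) return(m)
  for (i in 1:(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- superpose(frames[[i]], frames[[j]])$rmsd
    }
  }
  m
}

#' Default clustering selection: alpha carbons of the central residues
#'
#' The first and last residue of each chain are excluded; chain termini are
#' floppy and would blur the conformational classification.
#'
#' @param topology a \linkS4class{Topology} (or Conformation/Trajectory).
#' @return integer atom indices.
#' @export
centralCASelection <- function(topology) {
  a <- if (is(topology, "Topology")) topology@atoms else atomData(topology)
  keep <- integer(0)
  for (ch in unique(a$chain)) {
    nres <- max(a$resid[a$chain == ch])
    if (nres < 3L)
      stopf("chain %s is too short to have central residues", ch)
    keep <- c(keep, which(a$chain == ch & a$role == "CA" &
                            a$resid > 1L & a$resid < nres))
  }
  keep
}

#' Daura conformational clustering
#'
#' Iterative neighbor-count clustering on the pairwise superposed RMSD: the
#' frame with the most neighbors within the cutoff becomes a cluster center
#' (ties resolved toward the earliest frame); it and its neighbors are
#' removed and the procedure repeats until no frames remain.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param cutoff RMSD cutoff in nm (default 0.1).
#' @param selection atom indices used for the RMSD (default: alpha carbons of
#'   the central residues, \code{\link{centralCASelection}}).
#' @return a \linkS4class{ClusterResult}.
#' @export
dauraCluster <- function(traj, cutoff = 0.1,
                         selection = centralCASelection(traj)) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (length(selection) == 0L) stopf("empty clustering selection")
  nf <- nFrames(traj)
  rm_ <- pairwiseRMSD(traj, selection)
  neighbor <- rm_ <= cutoff     # includes self on the diagonal
  ids <- rep(NA_integer_, nf)
  centers <- integer(0)
  sizes <- integer(0)
  remaining <- rep(TRUE, nf)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(neighbor[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)   # earliest frame wins ties
    members <- which(neighbor[center, ] & remaining)
    ids[members] <- cl
    centers[cl] <- center
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  new("ClusterResult", ids = ids, centers = centers, sizes = sizes,
      cutoff = cutoff)
}

#' Cumulative cluster-count convergence curve
#'
#' The value at time t is the number of distinct conformational clusters
#' visited by frames with time <= t. A plateau indicates that the sampling
#' has stopped discovering new conformations.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param times frame times in ps, one per frame.
#' @return data.frame with columns `time_ps` and `clusters` (non-decreasing;
#'   the final value is the total cluster count).
#' @export
convergenceCurve <- function(result, times) {
  ids <- result@ids
  if (length(times) != length(ids))
    stopf("need one time per frame")
  cum <- cumsum(!duplicated(ids))
  data.frame(time_ps = times, clusters = cum)
}
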