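## Secondary-structure propensity scores and NOE violation analysis.

## H(i)...O(i+2) style distance pairs for one chain; pairs are dropped (from
## sum and normalization alike) only when the topology lacks the atoms.
helix_pairs <- function(a, chain) {
  sel <- a$chain == chain
  nres <- max(a$resid[sel])
  if (nres < 3L)
    stopf("helicity is undefined for chains of fewer than 3 residues")
  H <- vapply(seq_len(nres), function(r) {
    i <- which(sel & a$resid == r & a$role == "H")
    if (length(i) == 1L) i else NA_integer_
  }, integer(1L))
  O <- vapply(seq_len(nres), function(r) {
    i <- which(sel & a$resid == r & a$role == "O")
    if (length(i) == 1L) i else NA_integer_
  }, integer(1L))
  i <- seq_len(nres - 2L)
  keep <- !is.na(H[i]) & !is.na(O[i + 2L])
  if (!any(keep)) stopf("chain %s has no resolvable H(i)/O(i+2) pairs", chain)
  cbind(H = H[i][keep], O = O[i + 2L][keep])
}

series_over_frames <- function(traj, pair_sets, params, kind) {
  nf <- nFrames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- traj@coords[, , k]
    box <- if (nrow(traj@box) > 0L) traj@box[k, ] else NULL
    chain_scores <- vapply(pair_sets, function(p) {
      d <- minimumImageDistance(xyz[p[, 1L], , drop = FALSE],
                                xyz[p[, 2L], , drop = FALSE], box)
      mean(switchingScore(d, params))
    }, numeric(1L))
    vals[k] <- mean(chain_scores)
  }
  new("ScoreSeries", times = traj@times, values = vals, kind = kind)
}

#' Helical propensity score over a trajectory
#'
#' For a chain of N residues the per-frame score is the mean of the switching
#' score over the N - 2 distances between the amide proton of residue i and
#' the carbonyl oxygen of residue i + 2 (i = 1..N-2), the hydrogen-bond
#' fingerprint of the 14-helix. N - 2 is the largest possible number of such
#' bonds, so the score lies in [0, 1] and reads as a percentage helicity.
#' Residues whose amide H or carbonyl O is absent from the topology are
#' excluded from both the sum and the normalization. With several chains the
#' per-chain scores are averaged.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param params a \linkS4class{SwitchingParams} object.
#' @param chains chains to score (default: all).
#' @return a \linkS4class{ScoreSeries} of kind "helicity".
#' @export
#' @examples
#' trj <- synthesizeTrajectory(presetConformation("helix314", 6),
#'                             presetConformation("helix314", 6),
#'                             synthesisPlan(3, noiseSigma = 0))
#' mean(scoreValues(helicitySeries(trj)))
helicitySeries <- function(traj, params = switchingParams(), chains = NULL) {
  a <- atomData(traj)
  chains <- chains %||% unique(a$chain)
  pair_sets <- lapply(chains, function(ch) helix_pairs(a, ch))
  series_over_frames(traj, pair_sets, params, "helicity")
}

#' Designated hydrogen bonds of a hairpin fold
#'
#' @param pairs two-column matrix or data.frame of (donor residue, acceptor
#'   residue) indices. The default is the three-bond ladder of a six-residue
#'   hairpin: 3 -> 4 (the turn-flanking middle bond), 2 -> 5 and 1 -> 6.
#' @return data.frame with columns donor, acceptor.
#' @export
hairpinSpec <- function(pairs = cbind(donor = c(3, 2, 1),
                                      acceptor = c(4, 5, 6))) {
  p <- as.data.frame(pairs)
  names(p) <- c("donor", "acceptor")
  if (anyDuplicated(p) > 0L) stopf("designated bond pairs must be distinct")
  if (any(p < 1L)) stopf("residue indices must be 1-based")
  p
}

#' Hairpin likeness score over a trajectory
#'
#' Per frame, the mean of the switching score over the H...O distances of the
#' fold's designated hydrogen bonds (donor residue amide H to acceptor
#' residue carbonyl O). With exactly one of three designated bonds formed the
#' score is that bond's switching value divided by 3.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param spec a \code{\link{hairpinSpec}} listing the designated bonds.
#' @param params a \linkS4class{SwitchingParams} object.
#' @param chains chains to score (default: all).
#' @return a \linkS4class{ScoreSeries} of kind "hairpin".
#' @export
hairpinSeries <- function(traj, spec = hairpinSpec(),
                          params = switchingParams(), chains = NULL) {
  a <- atomData(traj)
  chains <- chains %||% unique(a$chain)
  pair_sets <- lapply(chains, function(ch) {
    H <- vapply(spec$donor, function(r) {
      i <- which(a$chain == ch & a$resid == r & a$role == "H")
      if (length(i) == 1L) i else NA_integer_
    }, integer(1L))
    O <- vapply(spec$acceptor, function(r) {
      i <- which(a$chain == ch & a$resid == r & a$role == "O")
      if (length(i) == 1L) i else NA_integer_
    }, integer(1L))
    if (anyNA(H) || anyNA(O))
      stopf("hairpin spec references residues absent from chain %s", ch)
    cbind(H = H, O = O)
  })
  series_over_frames(traj, pair_sets, params, "hairpin")
}

resolve_group <- function(a, chain, resid, names_piped) {
  nm <- strsplit(names_piped, "\\|")[[1L]]
  idx <- which(a$chain == chain & a$resid == resid & a$name %in% nm)
  if (length(idx) == 0L)
    stopf("NOE group (%s %d %s) matches no atoms", chain, resid, names_piped)
  idx
}

#' NOE upper-bound violation analysis
#'
#' For every restraint the instantaneous distance in a frame is the smallest
#' distance over all atom pairs of the two chemical-equivalence groups; the
#' effective distance is the r^-6 time average \eqn{\langle r^{-6}
#' \rangle^{-1/6}} over the averaging window, and the violation is the signed
#' difference to the experimental upper bound. Because the bounds are upper
#' thresholds, only positive violations indicate disagreement; they are
#' flagged.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param restraints data.frame as from \code{\link{readNOETable}}.
#' @param window time range c(start, end) in ps over which to average;
#'   default: the final 60 percent of frames.
#' @return data.frame with one row per restraint: `restraint`, `r_eff_nm`,
#'   `violation_nm`, `positive`, `window_start_ps`, `window_end_ps`.
#' @export
noeViolations <- function(traj, restraints, window = NULL) {
  a <- atomData(traj)
  tm <- traj@times
  nf <- length(tm)
  if (is.null(window)) {
    first <- nf - ceiling(0.6 * nf) + 1L
    window <- c(tm[first], tm[nf])
  }
  frames <- which(tm >= window[1L] & tm <= window[2L])
  if (length(frames) == 0L) stopf("averaging window contains no frames")
  out <- lapply(seq_len(nrow(restraints)), function(r) {
    gi <- resolve_group(a, restraints$chain_i[r], restraints$resid_i[r],
                        restraints$atom_names_i[r])
    gj <- resolve_group(a, restraints$chain_j[r], restraints$resid_j[r],
                        restraints$atom_names_j[r])
    if (length(intersect(gi, gj)) > 0L)
      stopf("NOE restraint %d: equivalence groups overlap", r)
    rmin <- vapply(frames, function(k) {
      xyz <- traj@coords[, , k]
      box <- if (nrow(traj@box) > 0L) traj@box[k, ] else NULL
      min(vapply(gi, function(p)
        min(minimumImageDistance(
          matrix(xyz[p, ], nrow = length(gj), ncol = 3L, byrow = TRUE),
          xyz[gj, , drop = FALSE], box)), numeric(1L)))
    }, numeric(1L))
    reff <- mean(rmin^(-6))^(-1 / 6)
    data.frame(restraint = r, r_eff_nm = reff,
               violation_nm = reff - restraints$r_exp_nm[r],
               positive = reff > restraints$r_exp_nm[r],
               window_start_ps = window[1L], window_end_ps = window[2L])
  })
  do.call(rbind, out)
}

#' Gaussian kernel density summary of a score series
#'
#' Presentation utility mirroring the density panels drawn beside score time
#' series; bandwidth by Scott's rule.
#'
#' @param series a \linkS4class{ScoreSeries}.
#' @return a stats::density object over the score values.
#' @export
scoreDensity <- function(series) {
  stats::density(series@values, bw = "nrd", from = 0, to = 1)
}

#' Export a score series as CSV
#'
#' @param series a \linkS4class{ScoreSeries}.
#' @param path output path; columns time_ps, score.
#' @return `path`, invisibly.
#' @export
writeScoreCSV <- function(series, path) {
  utils::write.csv(data.frame(time_ps = series@times,
                              score = series@values),
                   path, row.names = FALSE)
  invisible(path)
}
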