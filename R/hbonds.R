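## Hydrogen-bond analytics: the continuous switching-function score and the
## discrete geometric criterion, plus pooled residue-residue occupancy maps.

#' Continuous hydrogen-bond switching score
#'
#' Rational switching function of the hydrogen--acceptor-oxygen distance,
#' \deqn{s(d) = \frac{1 - (d/d_0)^n}{1 - (d/d_0)^m},}
#' continuously extended with \eqn{s(d_0) = n/m} and clamped to [0, 1].
#' It is 1 at contact, monotonically non-increasing in \eqn{d}, and with the
#' default parameters crosses 50\% at 0.27 nm and 10\% at 0.44 nm.
#'
#' @param d distance(s) in nm (>= 0); vectorized.
#' @param params a \linkS4class{SwitchingParams} object.
#' @return score(s) in [0, 1].
#' @export
#' @examples
#' switchingScore(c(0.27, 0.44), switchingParams())
switchingScore <- function(d, params = switchingParams()) {
  stopifnot(all(d >= 0))
  x <- d / params@d0
  s <- ifelse(abs(x - 1) < 1e-9,
              params@n / params@m,
              (1 - x^params@n) / (1 - x^params@m))
  pmin(1, pmax(0, s))
}

## Donor/acceptor registry: backbone amide N-H pairs donate, carbonyl O
## accept. Atom indices into the topology's atom table.
hbond_registry <- function(topology) {
  a <- if (is(topology, "Topology")) topology@atoms else atomData(topology)
  key <- paste(a$chain, a$resid)
  iN <- which(a$role == "N")
  iH <- which(a$role == "H")
  hmatch <- match(key[iN], key[iH])
  don <- data.frame(N = iN[!is.na(hmatch)],
                    H = iH[hmatch[!is.na(hmatch)]],
                    chain = a$chain[iN[!is.na(hmatch)]],
                    resid = a$resid[iN[!is.na(hmatch)]],
                    stringsAsFactors = FALSE)
  iO <- which(a$role == "O")
  acc <- data.frame(O = iO, chain = a$chain[iO], resid = a$resid[iO],
                    stringsAsFactors = FALSE)
  list(donors = don, acceptors = acc)
}

detect_frame_events <- function(xyz, reg, criteria, scope, box = NULL) {
  don <- reg$donors
  acc <- reg$acceptors
  out <- list()
  if (nrow(don) == 0L || nrow(acc) == 0L)
    return(NULL)
  mic <- function(p, q) {
    d <- p - q
    if (!is.null(box)) d <- d - box * round(d / box)
    d
  }
  for (i in seq_len(nrow(don))) {
    vNH <- mic(xyz[don$H[i], ], xyz[don$N[i], ])
    if (vnorm(vNH) >= criteria@maxDonorH) next
    for (j in seq_len(nrow(acc))) {
      same_chain <- don$chain[i] == acc$chain[j]
      if (scope == "intrachain" && !same_chain) next
      if (scope == "interchain" && same_chain) next
      vNA <- mic(xyz[acc$O[j], ], xyz[don$N[i], ])
      dNA <- vnorm(vNA)
      if (dNA >= criteria@maxDonorAcceptor) next
      ## D-H-A angle at the hydrogen; acceptor taken at its minimum image
      vHN <- -vNH
      vHA <- vNA - vNH
      ang <- rad2deg(acos(max(-1, min(1,
        sum(vHN * vHA) / (vnorm(vHN) * vnorm(vHA))))))
      if (ang <= criteria@minAngle) next
      out[[length(out) + 1L]] <- data.frame(
        donor = don$N[i], hydrogen = don$H[i], acceptor = acc$O[j],
        donorChain = don$chain[i], donorResid = don$resid[i],
        acceptorChain = acc$chain[j], acceptorResid = acc$resid[j],
        distance = dNA, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Detect hydrogen bonds with the discrete geometric criterion
#'
#' A donor/hydrogen/acceptor triple counts as bonded when the donor--acceptor
#' distance is below the cutoff, the donor-hydrogen-acceptor angle exceeds
#' the angle cutoff and the hydrogen lies within the donor-hydrogen cutoff of
#' its donor. Donors are backbone amide N-H pairs, acceptors carbonyl O
#' atoms. Distances use the minimum-image convention whenever the trajectory
#' carries a box.
#'
#' @param x a \linkS4class{Conformation} or \linkS4class{Trajectory}.
#' @param criteria an \linkS4class{HBondCriteria} object.
#' @param scope "all", "intrachain" or "interchain".
#' @param frames frame indices to analyse (Trajectory only; default all).
#' @return data.frame of events with one row per bond: `frame`, atom indices
#'   `donor`, `hydrogen`, `acceptor`, donor/acceptor chain and residue,
#'   donor-acceptor `distance` (nm) and D-H-A `angle` (degrees).
#' @export
detectHBonds <- function(x, criteria = hbondCriteria(),
                         scope = c("all", "intrachain", "interchain"),
                         frames = NULL) {
  scope <- match.arg(scope)
  reg <- hbond_registry(x)
  empty <- data.frame(frame = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      donorChain = character(0), donorResid = integer(0),
                      acceptorChain = character(0),
                      acceptorResid = integer(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  if (is(x, "Conformation")) {
    ev <- detect_frame_events(x@coords, reg, criteria, scope)
    if (is.null(ev)) return(empty)
    return(cbind(frame = 1L, ev))
  }
  frames <- frames %||% seq_len(nFrames(x))
  res <- lapply(frames, function(k) {
    box <- if (nrow(x@box) > 0L) x@box[k, ] else NULL
    ev <- detect_frame_events(x@coords[, , k], reg, criteria, scope, box)
    if (is.null(ev)) NULL else cbind(frame = k, ev)
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Residue-residue hydrogen-bond occupancy map
#'
#' Entry (i, j) is the percentage of pooled frames, over one or more
#' independent runs of the same system, in which at least one hydrogen bond
#' links donor residue i to acceptor residue j. Residues are indexed 1-based
#' within their chain; when several chains are present, bonds from all chains
#' are pooled by residue index.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of them (independent
#'   reruns); all must share a topology.
#' @param criteria an \linkS4class{HBondCriteria} object.
#' @param scope "intrachain" (default), "interchain" or "all".
#' @return an \linkS4class{OccupancyMap}.
#' @export
occupancyMap <- function(trajectories, criteria = hbondCriteria(),
                         scope = c("intrachain", "interchain", "all")) {
  scope <- match.arg(scope)
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  topo <- trajectories[[1L]]@topology
  for (tr in trajectories)
    if (!identical(atomData(tr), topo@atoms))
      stopf("all pooled runs must share one topology")
  nres <- max(topo@atoms$resid)
  counts <- matrix(0L, nres, nres,
                   dimnames = list(donor = seq_len(nres),
                                   acceptor = seq_len(nres)))
  total <- 0L
  for (tr in trajectories) {
    ev <- detectHBonds(tr, criteria, scope)
    total <- total + nFrames(tr)
    if (nrow(ev) == 0L) next
    key <- unique(ev[, c("frame", "donorResid", "acceptorResid")])
    tab <- table(factor(key$donorResid, levels = seq_len(nres)),
                 factor(key$acceptorResid, levels = seq_len(nres)))
    counts <- counts + unclass(tab)
  }
  new("OccupancyMap", percent = 100 * counts / total,
      nFrames = as.integer(total), nRuns = length(trajectories),
      scope = scope)
}

#' Export an occupancy map as CSV
#'
#' Rows are donor residues, columns acceptor residues.
#'
#' @param map an \linkS4class{OccupancyMap}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOccupancyCSV <- function(map, path) {
  utils::write.csv(as.data.frame(map@percent), path, row.names = TRUE)
  invisible(path)
}
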