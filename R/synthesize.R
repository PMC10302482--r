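## Synthetic pseudo-trajectories: the stand-in for expensive MD sampling.
## Single chains interpolate backbone torsions between two conformations with
## Gaussian positional noise; multichain boxes form and break hydrogen-bonded
## associates on a scripted schedule.

## torsions suitable for rebuilding: psi of the last residue is recovered from
## the carbonyl O placement; unused end torsions default to 180
rebuild_torsions <- function(conf, chain = NULL) {
  tor <- backboneTorsions(conf, chain)
  nres <- nrow(tor)
  a <- atomData(conf)
  chain <- chain %||% a$chain[1L]
  sel <- a$chain == chain
  ac <- a[sel, , drop = FALSE]
  xyz <- conf@coords[sel, , drop = FALSE]
  at <- function(res, role) xyz[which(ac$resid == res & ac$role == role), ]
  tor$psi[nres] <- wrap180(dihedral_angle(at(nres, "CB"), at(nres, "CA"),
                                          at(nres, "C"), at(nres, "O")) - 180)
  ## phi of residue 1 only orients the N-terminal amide H; recover it from
  ## the H position so rebuilding preserves that hydrogen exactly
  h1 <- which(ac$resid == 1L & ac$role == "H")
  tor$phi[1L] <- if (length(h1) == 1L)
    wrap180(dihedral_angle(at(1L, "CA"), at(1L, "CB"), at(1L, "N"),
                           xyz[h1, ]) + 180) else 180
  tor$omega[1L] <- 180
  tor
}

#' Build an ideal single-chain conformation from a torsion preset
#'
#' @param preset preset name, see \code{\link{torsionPreset}}.
#' @param n number of residues.
#' @param residue residue template code used for every position.
#' @param templates residue template registry.
#' @return a \linkS4class{Conformation}.
#' @export
#' @examples
#' presetConformation("extended", 6)
presetConformation <- function(preset, n, residue = "B3A",
                               templates = defaultResidueTemplates()) {
  buildBackbone(rep(residue, n), torsionPreset(preset, n), templates)
}

#' Synthesize a single-chain pseudo-trajectory between two conformations
#'
#' Backbone torsions are measured on both endpoint conformations and
#' interpolated linearly along the shortest angular path; each frame is
#' rebuilt by internal-coordinate placement and i.i.d. Gaussian noise of
#' standard deviation `plan$noiseSigma` is added to every atom coordinate.
#' Frame k carries the timestamp k * dt (ps). Identical seeds give identical
#' trajectories. With `start == end` and zero noise all frames equal the
#' start conformation.
#'
#' @param confStart,confEnd single-chain \linkS4class{Conformation}s sharing
#'   one topology.
#' @param plan a \code{\link{synthesisPlan}}.
#' @param templates residue template registry used for rebuilding.
#' @return a \linkS4class{Trajectory}.
#' @export
#' @examples
#' hel <- presetConformation("helix314", 6)
#' ext <- presetConformation("extended", 6)
#' trj <- synthesizeTrajectory(ext, hel, synthesisPlan(5, noiseSigma = 0))
#' nFrames(trj)
synthesizeTrajectory <- function(confStart, confEnd, plan,
                                 templates = defaultResidueTemplates()) {
  if (!identical(atomData(confStart), atomData(confEnd)))
    stopf("start and end conformations must share a topology")
  a <- atomData(confStart)
  if (length(unique(a$chain)) != 1L)
    stopf("trajectory synthesis works on single chains")
  seqv <- a$resname[a$role == "N"]
  t0 <- rebuild_torsions(confStart)
  t1 <- rebuild_torsions(confEnd)
  nf <- plan$nFrames
  frac <- if (nf == 1L) 0 else (seq_len(nf) - 1L) / (nf - 1L)

  natoms <- nrow(a)
  co <- array(NA_real_, dim = c(natoms, 3L, nf))
  with_seed(plan$seed, {
    for (k in seq_len(nf)) {
      tk <- t0
      for (col in c("phi", "theta", "psi", "omega")) {
        tk[[col]] <- t0[[col]] + frac[k] * wrap180(t1[[col]] - t0[[col]])
      }
      fr <- buildBackbone(seqv, tk, templates, chain = a$chain[1L])
      co[, , k] <- fr@coords +
        matrix(stats::rnorm(natoms * 3L, sd = plan$noiseSigma), ncol = 3L)
    }
  })
  new("Trajectory", topology = confStart@topology, coords = co,
      times = (seq_len(nf) - 1L) * plan$dt,
      box = matrix(numeric(0), nrow = 0L, ncol = 3L))
}

## Rodrigues rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antiparallel: rotate pi about any axis perpendicular to a
    p <- cross3(a, c(1, 0, 0))
    if (vnorm(p) < 1e-10) p <- cross3(a, c(0, 1, 0))
    p <- unitv(p)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               nrow = 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Default docking schedule for an association box
#'
#' Scripted contact windows producing a transient dimer that temporarily
#' grows into a trimer, plus an independent second dimer, within an
#' `nFrames`-frame run.
#'
#' @param nFrames number of frames of the planned trajectory.
#' @return data.frame with columns chainFrom, chainOnto, dockResid,
#'   hostResid, from, to (frame indices, 1-based).
#' @export
defaultAssociationSchedule <- function(nFrames) {
  f <- function(x) max(1L, min(nFrames, as.integer(round(x * nFrames))))
  data.frame(
    chainFrom = c("B", "C", "E"),
    chainOnto = c("A", "B", "D"),
    dockResid = 2L,
    hostResid = 3L,
    from = c(f(0.10), f(0.25), f(0.60)),
    to   = c(f(0.50), f(0.40), f(0.75)),
    stringsAsFactors = FALSE)
}

#' Synthesize a multichain box with transient hydrogen-bonded associates
#'
#' Assembles `nCopies` randomly rotated copies of a chain on a cubic grid and,
#' on a scripted schedule of contact windows, docks chains onto each other so
#' that a near-linear interchain N-H...O=C hydrogen bond (H...O 0.19 nm)
#' exists for the duration of the window. Docking is transitive: a chain
#' docked onto an already-docked chain extends the hydrogen-bond network, so
#' the schedule controls when dimers, trimers, ... are alive. Gaussian noise
#' is added to every coordinate of every frame.
#'
#' @param conf single-chain \linkS4class{Conformation}.
#' @param nCopies number of chains (perfect cube, default 8).
#' @param spacing cubic grid spacing in nm.
#' @param plan a \code{\link{synthesisPlan}} (noiseSigma should stay well
#'   below 0.01 nm so scripted bonds survive the noise).
#' @param schedule contact windows as from
#'   \code{\link{defaultAssociationSchedule}}.
#' @return a multichain \linkS4class{Trajectory}.
#' @export
synthesizeAssociation <- function(conf, nCopies = 8L, spacing = 3,
                                  plan = synthesisPlan(200, noiseSigma = 0.002),
                                  schedule = defaultAssociationSchedule(plan$nFrames)) {
  base <- assembleMultichain(conf, nCopies, spacing, seed = plan$seed)
  a <- atomData(base)
  natoms <- nrow(a)
  nf <- plan$nFrames
  co <- array(NA_real_, dim = c(natoms, 3L, nf))
  chain_rows <- split(seq_len(natoms), a$chain)

  dock_pose <- function(xyz, ev) {
    host <- chain_rows[[ev$chainOnto]]
    mob <- chain_rows[[ev$chainFrom]]
    iO <- host[a$resid[host] == ev$hostResid & a$role[host] == "O"]
    iN <- mob[a$resid[mob] == ev$dockResid & a$role[mob] == "N"]
    iH <- mob[a$resid[mob] == ev$dockResid & a$role[mob] == "H"]
    if (length(iO) != 1L || length(iN) != 1L || length(iH) != 1L)
      stopf("docking schedule references atoms missing from the topology")
    O <- xyz[iO, ]
    w <- unitv(O - colMeans(xyz[host, , drop = FALSE]))
    u <- -w                               # N->H direction after docking
    R <- rotation_between(xyz[iH, ] - xyz[iN, ], u)
    Hnew <- O + 0.19 * w
    old_H <- xyz[iH, ]
    xyz[mob, ] <- sweep(t(R %*% t(sweep(xyz[mob, , drop = FALSE], 2L, old_H))),
                        2L, Hnew, FUN = "+")
    xyz
  }

  with_seed(plan$seed + 1L, {
    for (k in seq_len(nf)) {
      xyz <- base@coords
      if (nrow(schedule) > 0L) {
        for (e in seq_len(nrow(schedule))) {
          ev <- schedule[e, ]
          if (k >= ev$from && k <= ev$to) xyz <- dock_pose(xyz, ev)
        }
      }
      co[, , k] <- xyz +
        matrix(stats::rnorm(natoms * 3L, sd = plan$noiseSigma), ncol = 3L)
    }
  })
  new("Trajectory", topology = base@topology, coords = co,
      times = (seq_len(nf) - 1L) * plan$dt,
      box = matrix(numeric(0), nrow = 0L, ncol = 3L))
}
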