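## Residue templates and torsion presets: the configuration data behind the
## synthetic-structure builder.

#' Construct a beta-amino acid residue template
#'
#' A template fixes the backbone atoms of one residue in internal coordinates:
#' for each atom its bond length to the preceding main-chain atom and the bond
#' angle at that atom. The backbone atom order of a beta-amino acid is
#' N, H (optional), CB (beta carbon), CA (alpha carbon), C, O. Cyclic residues
#' (ACPC/ACHC-like) do not get an explicit ring; instead the ring constraint is
#' expressed by clamping the theta backbone torsion (`thetaClamp`), which is
#' all the backbone hydrogen-bond analytics need.
#'
#' @param name three-letter residue code.
#' @param backboneAtoms data.frame with columns `name`, `element`, `bond`
#'   (nm, to the preceding main-chain atom) and `angle` (degrees).
#' @param hasAmideH does the residue carry a backbone amide hydrogen?
#' @param thetaClamp optional fixed value (degrees) for the CB-CA torsion
#'   imposed by a ring, or `NA` for acyclic residues.
#' @param sideChain optional single pseudo-atom side chain attached to CB,
#'   given as c(bond, angle, dihedral) (nm, degrees, degrees), or `NULL`.
#' @return a list of class `ResidueTemplate`.
#' @export
#' @examples
#' tpl <- defaultResidueTemplates()[["B3A"]]
#' tpl$name
residueTemplate <- function(name, backboneAtoms, hasAmideH = TRUE,
                            thetaClamp = NA_real_, sideChain = NULL) {
  stopifnot(is.data.frame(backboneAtoms))
  expected <- if (hasAmideH) c("N", "H", "CB", "CA", "C", "O") else
    c("N", "CB", "CA", "C", "O")
  if (!identical(backboneAtoms$name, expected))
    stopf("backbone atom order must be %s", paste(expected, collapse = ", "))
  if (any(backboneAtoms$bond <= 0.05 | backboneAtoms$bond >= 0.25))
    stopf("bond lengths must lie in (0.05, 0.25) nm")
  if (any(backboneAtoms$angle <= 60 | backboneAtoms$angle >= 180))
    stopf("bond angles must lie in (60, 180) degrees")
  structure(list(name = name, backboneAtoms = backboneAtoms,
                 hasAmideH = hasAmideH, thetaClamp = thetaClamp,
                 sideChain = sideChain),
            class = "ResidueTemplate")
}

## standard amide/aliphatic geometry, shared by all shipped templates
.beta_backbone_geometry <- function() {
  data.frame(
    name    = c("N",   "H",   "CB",  "CA",  "C",   "O"),
    element = c("N",   "H",   "C",   "C",   "C",   "O"),
    ## bond to preceding main-chain atom: C(-1)-N, N-H, N-CB, CB-CA, CA-C, C=O
    bond    = c(0.133, 0.101, 0.146, 0.153, 0.152, 0.123),
    ## angle at the new atom's anchor: CA(-1)-C(-1)-N, C(-1)-N-H, C(-1)-N-CB,
    ## N-CB-CA, CB-CA-C, CA-C-O
    angle   = c(116,   119,   122,   111,   111,   121),
    stringsAsFactors = FALSE)
}

#' Built-in residue templates
#'
#' \describe{
#'   \item{B3A}{generic acyclic beta-3 residue, backbone only.}
#'   \item{B3S}{acyclic beta-3 residue with a single side-chain pseudo-atom
#'     (CS) on the beta carbon.}
#'   \item{ACP}{ACPC-like cyclic residue; the cyclopentane ring clamps the
#'     backbone theta torsion near 89 degrees.}
#'   \item{ACH}{ACHC-like cyclic residue; the cyclohexane ring clamps theta
#'     near 55 degrees.}
#' }
#'
#' @return named list of `ResidueTemplate` objects.
#' @export
defaultResidueTemplates <- function() {
  geo <- .beta_backbone_geometry()
  list(
    B3A = residueTemplate("B3A", geo),
    B3S = residueTemplate("B3S", geo,
                          sideChain = c(bond = 0.153, angle = 110,
                                        dihedral = -122)),
    ACP = residueTemplate("ACP", geo, thetaClamp = 89),
    ACH = residueTemplate("ACH", geo, thetaClamp = 55)
  )
}

## Preset backbone torsions (degrees). These are configuration data: the
## numbers are not measurements but idealised values chosen so that the built
## geometry forms the hydrogen bonds that define each fold (see the methods
## vignette). They are validated functionally in the test suite through the
## H...O distances of the designated bonds.
## Idealised torsions calibrated so each fold's designated N-H...O=C bonds
## come out linear with N...O = 0.255 nm (H...O = 0.154 nm), satisfying both
## the discrete detection criteria and a near-saturated switching score.
.torsion_presets <- list(
  extended = c(phi = 180, theta = 180, psi = 180),
  helix314 = c(phi = -132.05, theta = 54.73, psi = -133.92),
  helix2512 = c(phi = 96.66, theta = -88.78, psi = 96.08)
)

## hairpin: two strands joined by a two-residue turn (residues 3-4), tuned
## for a six-residue chain so the designated bonds 3 -> 4, 2 -> 5 and
## 1 -> 6 are all linear at N...O = 0.255 nm
.hairpin_torsions_n6 <- data.frame(
  phi   = c(101.20, 101.20, 119.69, 58.81, 101.20, 101.20),
  theta = c(-172.08, -172.08, 61.26, 49.13, -172.08, -172.08),
  psi   = c(-100.16, -100.16, 22.79, 166.70, -100.16, -100.16),
  omega = 180
)

#' Backbone torsion presets for ideal secondary structures
#'
#' Returns one row of (phi, theta, psi, omega) per residue, in degrees, for an
#' idealised conformation. `extended`, `helix314` (the 14-helix with
#' NH(i)...O=C(i+2) bonds) and `helix2512` (the 12-helix with i -> i-3 bonds)
#' are uniform along the chain; `hairpin` is a per-residue table (two strands
#' and a central turn) defined for chains of six residues.
#'
#' @param name one of "extended", "helix314", "helix2512", "hairpin".
#' @param n number of residues.
#' @return data.frame with columns phi, theta, psi, omega and `n` rows.
#' @export
#' @examples
#' torsionPreset("helix314", 6)
torsionPreset <- function(name, n) {
  stopifnot(n >= 1)
  if (name == "hairpin") {
    if (n != 6L)
      stopf("the hairpin preset is defined for 6-residue chains (got %d)", n)
    return(.hairpin_torsions_n6)
  }
  if (!name %in% names(.torsion_presets))
    stopf("unknown torsion preset '%s'", name)
  p <- .torsion_presets[[name]]
  data.frame(phi = rep(p[["phi"]], n), theta = rep(p[["theta"]], n),
             psi = rep(p[["psi"]], n), omega = rep(180, n))
}

#' Switching-function parameters
#'
#' @param d0 reference distance in nm (default 0.25).
#' @param n numerator exponent (default 6).
#' @param m denominator exponent (default 10). The defaults put the 50%
#'   crossing of the score at 0.27 nm and the 10% crossing at 0.44 nm.
#' @return a \linkS4class{SwitchingParams} object.
#' @export
#' @examples
#' switchingScore(0.27, switchingParams())
switchingParams <- function(d0 = 0.25, n = 6, m = 10) {
  new("SwitchingParams", d0 = d0, n = n, m = m)
}

#' Discrete hydrogen-bond criteria
#'
#' @param maxDonorAcceptor donor--acceptor heavy-atom cutoff, nm (default 0.3).
#' @param minAngle donor-hydrogen-acceptor angle cutoff, degrees (default 150).
#' @param maxDonorH maximal donor--hydrogen distance, nm (default 0.12).
#' @return an \linkS4class{HBondCriteria} object.
#' @export
hbondCriteria <- function(maxDonorAcceptor = 0.3, minAngle = 150,
                          maxDonorH = 0.12) {
  new("HBondCriteria", maxDonorAcceptor = maxDonorAcceptor,
      minAngle = minAngle, maxDonorH = maxDonorH)
}

#' Plan for synthesizing a pseudo-trajectory
#'
#' @param nFrames number of frames (>= 1).
#' @param dt time step between frames in ps (> 0).
#' @param noiseSigma standard deviation of the i.i.d. Gaussian positional
#'   noise added per atom coordinate, nm (>= 0).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param start,end optional preset names recording what the endpoints are.
#' @return a list of class `SynthesisPlan`.
#' @export
synthesisPlan <- function(nFrames, dt = 100, noiseSigma = 0.01, seed = 1L,
                          start = NULL, end = NULL) {
  if (nFrames < 1) stopf("nFrames must be >= 1")
  if (dt <= 0) stopf("dt must be positive")
  if (noiseSigma < 0) stopf("noiseSigma must be >= 0")
  structure(list(nFrames = as.integer(nFrames), dt = dt,
                 noiseSigma = noiseSigma, seed = as.integer(seed),
                 start = start, end = end),
            class = "SynthesisPlan")
}
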