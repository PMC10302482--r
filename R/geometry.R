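## Internal-coordinate geometry: NeRF-style atom placement and torsion
## measurement. All distances in nm, all angles in degrees.

## Place atom D bonded to C, given reference atoms A-B-C, so that
## |CD| = bond, angle(B,C,D) = theta and dihedral(A,B,C,D) = phi.
place_atom <- function(A, B, C, bond, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  u <- unitv(C - B)              # along the anchor bond
  n <- cross3(B - A, u)
  if (vnorm(n) < 1e-10) {
    ## collinear reference frame: pick any perpendicular
    n <- cross3(u, c(1, 0, 0))
    if (vnorm(n) < 1e-10) n <- cross3(u, c(0, 1, 0))
  }
  n <- unitv(n)
  m <- cross3(n, u)
  d <- bond * (-cos(th) * u + sin(th) * (cos(ph) * m + sin(ph) * n))
  C + d
}

## Dihedral angle A-B-C-D in degrees, atan2 formulation, in [-180, 180).
dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2)))
}

## Bond angle at B in degrees.
bond_angle <- function(A, B, C) {
  u <- unitv(A - B)
  v <- unitv(C - B)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Measure backbone torsions from coordinates
#'
#' Recomputes the per-residue backbone torsions (phi, theta, psi, omega) of
#' one chain from Cartesian coordinates. Torsions that need atoms of a
#' neighbouring residue are `NA` at the chain ends: phi and omega of residue 1
#' and psi of the last residue involve no preceding/following residue.
#'
#' The conventions are those of beta-peptides: phi = C(i-1)-N-CB-CA,
#' theta = N-CB-CA-C, psi = CB-CA-C-N(i+1), omega = CA(i-1)-C(i-1)-N-CB.
#'
#' @param conf a \linkS4class{Conformation}.
#' @param chain chain id (default: the first chain).
#' @return data.frame with columns phi, theta, psi, omega in degrees.
#' @export
#' @examples
#' conf <- buildBackbone(rep("B3A", 4), torsionPreset("helix314", 4))
#' backboneTorsions(conf)
backboneTorsions <- function(conf, chain = NULL) {
  a <- atomData(conf)
  chain <- chain %||% a$chain[1L]
  sel <- which(a$chain == chain)
  ac <- a[sel, , drop = FALSE]
  xyz <- conf@coords[sel, , drop = FALSE]
  nres <- max(ac$resid)
  idx <- function(res, role) {
    i <- which(ac$resid == res & ac$role == role)
    if (length(i) != 1L) NA_integer_ else i
  }
  at <- function(i) xyz[i, ]
  out <- data.frame(phi = rep(NA_real_, nres), theta = NA_real_,
                    psi = NA_real_, omega = NA_real_)
  for (r in seq_len(nres)) {
    iN <- idx(r, "N"); iCB <- idx(r, "CB"); iCA <- idx(r, "CA")
    iC <- idx(r, "C")
    if (r > 1L) {
      iCp <- idx(r - 1L, "C"); iCAp <- idx(r - 1L, "CA")
      out$phi[r] <- dihedral_angle(at(iCp), at(iN), at(iCB), at(iCA))
      out$omega[r] <- dihedral_angle(at(iCAp), at(iCp), at(iN), at(iCB))
    }
    out$theta[r] <- dihedral_angle(at(iN), at(iCB), at(iCA), at(iC))
    if (r < nres) {
      iNn <- idx(r + 1L, "N")
      out$psi[r] <- dihedral_angle(at(iCB), at(iCA), at(iC), at(iNn))
    }
  }
  out
}
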