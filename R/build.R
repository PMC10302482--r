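## Backbone builder: sequential internal-coordinate (NeRF) chain construction
## and multichain box assembly.

#' Create a Topology from an atom table
#'
#' @param atoms data.frame with columns name, element, chain, resid, resname,
#'   role.
#' @return a \linkS4class{Topology}.
#' @export
makeTopology <- function(atoms) {
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms)
}

#' Build a beta-peptide backbone from torsion angles
#'
#' Constructs a single chain by sequential internal-coordinate placement: each
#' atom is positioned from the three preceding main-chain atoms using the
#' template bond length, bond angle and the requested torsion. Measuring the
#' torsions back from the returned coordinates (\code{\link{backboneTorsions}})
#' reproduces the inputs. Cyclic residue templates clamp the theta torsion to
#' their ring-imposed value regardless of the requested one.
#'
#' @param sequence character vector of residue template codes.
#' @param torsions data.frame with one row per residue and columns phi, theta,
#'   psi (and optionally omega, default 180), in degrees.
#' @param templates named list of residue templates
#'   (default \code{\link{defaultResidueTemplates}()}).
#' @param chain chain identifier for the built chain.
#' @return a \linkS4class{Conformation}.
#' @export
#' @examples
#' helix <- buildBackbone(rep("B3A", 6), torsionPreset("helix314", 6))
#' nAtoms(helix)
buildBackbone <- function(sequence, torsions,
                          templates = defaultResidueTemplates(),
                          chain = "A") {
  n <- length(sequence)
  if (n < 1L) stopf("sequence must be non-empty")
  if (!is.data.frame(torsions) || nrow(torsions) != n)
    stopf("need one torsion set per residue (%d residues, %d torsion rows)",
          n, if (is.data.frame(torsions)) nrow(torsions) else 0L)
  unknown <- setdiff(sequence, names(templates))
  if (length(unknown) > 0L)
    stopf("no residue template for code(s): %s",
          paste(unique(unknown), collapse = ", "))
  if (is.null(torsions$omega)) torsions$omega <- 180

  atoms <- list()
  xyz <- list()
  ## main-chain bookkeeping for placement references
  mc <- list()  # per residue: list(N=, CB=, CA=, C=)

  for (r in seq_len(n)) {
    tpl <- templates[[sequence[r]]]
    geo <- tpl$backboneAtoms
    g <- function(nm, col) geo[geo$name == nm, col]
    theta <- if (!is.na(tpl$thetaClamp)) tpl$thetaClamp else torsions$theta[r]

    if (r == 1L) {
      N <- c(0, 0, 0)
      CB <- c(g("CB", "bond"), 0, 0)
      aCA <- deg2rad(g("CA", "angle"))
      CA <- CB + g("CA", "bond") * c(cos(pi - aCA), sin(pi - aCA), 0)
      C <- place_atom(N, CB, CA, g("C", "bond"), g("C", "angle"), theta)
      ## phi of residue 1 has no preceding carbonyl to rotate about; it is
      ## used here to orient the N-terminal amide hydrogen consistently with
      ## the interior residues (H sits at phi - 180 about the N-CB axis)
      H <- if (tpl$hasAmideH)
        place_atom(CA, CB, N, g("H", "bond"), g("H", "angle"),
                   torsions$phi[1L] - 180)
    } else {
      prev <- mc[[r - 1L]]
      N <- place_atom(prev$CB, prev$CA, prev$C,
                      g("N", "bond"), g("N", "angle"), torsions$psi[r - 1L])
      CB <- place_atom(prev$CA, prev$C, N,
                       g("CB", "bond"), g("CB", "angle"), torsions$omega[r])
      H <- if (tpl$hasAmideH)
        place_atom(prev$CA, prev$C, N, g("H", "bond"), g("H", "angle"),
                   torsions$omega[r] - 180)
      CA <- place_atom(prev$C, N, CB, g("CA", "bond"), g("CA", "angle"),
                       torsions$phi[r])
      C <- place_atom(N, CB, CA, g("C", "bond"), g("C", "angle"), theta)
    }
    O <- place_atom(CB, CA, C, g("O", "bond"), g("O", "angle"),
                    torsions$psi[r] + 180)
    mc[[r]] <- list(N = N, CB = CB, CA = CA, C = C)

    res_names <- c("N", if (tpl$hasAmideH) "H", "CB", "CA", "C", "O")
    res_xyz <- rbind(N, if (tpl$hasAmideH) H, CB, CA, C, O)
    res_elem <- geo$element[match(res_names, geo$name)]
    res_role <- res_names
    if (!is.null(tpl$sideChain)) {
      sc <- tpl$sideChain
      CS <- place_atom(C, CA, CB, sc[["bond"]], sc[["angle"]],
                       sc[["dihedral"]])
      res_names <- c(res_names, "CS")
      res_xyz <- rbind(res_xyz, CS)
      res_elem <- c(res_elem, "C")
      res_role <- c(res_role, "other")
    }
    atoms[[r]] <- data.frame(name = res_names, element = res_elem,
                             chain = chain, resid = r,
                             resname = tpl$name, role = res_role,
                             stringsAsFactors = FALSE)
    xyz[[r]] <- res_xyz
  }

  topo <- makeTopology(do.call(rbind, atoms))
  co <- do.call(rbind, xyz)
  dimnames(co) <- NULL
  new("Conformation", topology = topo, coords = co)
}

## uniform random proper rotation from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' Assemble randomly rotated copies of a chain on a cubic grid
#'
#' Places `nCopies` copies of the input conformation at the nodes of a
#' k x k x k cubic grid (k = nCopies^(1/3), e.g. a 2 x 2 x 2 arrangement for
#' eight chains), applying an independent uniformly random proper rotation to
#' each copy about its own centroid. Chains are relabelled A, B, C, ...
#'
#' @param conf single-chain \linkS4class{Conformation}.
#' @param nCopies number of copies; must be a perfect cube.
#' @param spacing grid spacing in nm; should exceed the chain diameter.
#' @param seed integer seed for the random rotations.
#' @return a multichain \linkS4class{Conformation}.
#' @export
assembleMultichain <- function(conf, nCopies = 8L, spacing, seed = 1L) {
  k <- round(nCopies^(1 / 3))
  if (k^3 != nCopies)
    stopf("nCopies must be a perfect cube (got %d)", nCopies)
  a <- atomData(conf)
  if (length(unique(a$chain)) != 1L)
    stopf("input conformation must be single-chain")
  cent <- colMeans(conf@coords)
  grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                z = seq_len(k))) * spacing
  ids <- make.unique(rep(LETTERS, length.out = nCopies), sep = "")
  with_seed(seed, {
    pieces <- lapply(seq_len(nCopies), function(i) {
      R <- random_rotation()
      sweep(t(R %*% t(sweep(conf@coords, 2L, cent))), 2L,
            grid[i, ], FUN = "+")
    })
    co <- do.call(rbind, pieces)
  })
  atoms <- do.call(rbind, lapply(seq_len(nCopies), function(i) {
    ai <- a
    ai$chain <- ids[i]
    ai
  }))
  dimnames(co) <- NULL
  new("Conformation", topology = makeTopology(atoms), coords = co)
}
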