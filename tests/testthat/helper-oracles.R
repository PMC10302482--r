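## Independent oracles used across the suite. These deliberately re-derive
## quantities from first principles (brute force, closed forms, reference
## library calls) and never share code with the implementation they check.

wrapd <- function(x) ((x + 180) %% 360) - 180

## dihedral angle by the normal-vector/acos formulation with a triple-product
## sign (independent of the package's atan2 formulation)
oracle_dihedral <- function(A, B, C, D) {
  n1 <- pracma_cross(B - A, C - B)
  n2 <- pracma_cross(C - B, D - C)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(pracma_cross(n1, n2) * (C - B)) < 0) ang <- -ang
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## brute-force hydrogen-bond detection: exhaustive triple loop over all
## (N,H) donor pairs and O acceptors with direct formulas
oracle_hbonds <- function(xyz, atoms, criteria, scope = "all", box = NULL) {
  mic <- function(p, q) {
    d <- p - q
    if (!is.null(box)) d <- d - box * round(d / box)
    d
  }
  hits <- list()
  for (iN in which(atoms$role == "N")) {
    iH <- which(atoms$role == "H" & atoms$chain == atoms$chain[iN] &
                  atoms$resid == atoms$resid[iN])
    if (length(iH) != 1L) next
    dNH <- sqrt(sum(mic(xyz[iH, ], xyz[iN, ])^2))
    for (iO in which(atoms$role == "O")) {
      same <- atoms$chain[iO] == atoms$chain[iN]
      if (scope == "intrachain" && !same) next
      if (scope == "interchain" && same) next
      dNO <- sqrt(sum(mic(xyz[iO, ], xyz[iN, ])^2))
      vHN <- mic(xyz[iN, ], xyz[iH, ])
      vHO <- mic(xyz[iO, ], xyz[iN, ]) - mic(xyz[iH, ], xyz[iN, ])
      ang <- acos(max(-1, min(1, sum(vHN * vHO) /
                                (sqrt(sum(vHN^2)) * sqrt(sum(vHO^2)))))) *
        180 / pi
      if (dNH < criteria@maxDonorH && dNO < criteria@maxDonorAcceptor &&
            ang > criteria@minAngle)
        hits[[length(hits) + 1L]] <- c(iN, iH, iO)
    }
  }
  if (length(hits) == 0L) matrix(integer(0), ncol = 3L) else
    do.call(rbind, hits)
}

## depth-first-search connected components (checks Hoshen-Kopelman labeling)
oracle_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      adj[[edges$a[e]]] <- c(adj[[edges$a[e]]], edges$b[e])
      adj[[edges$b[e]]] <- c(adj[[edges$b[e]]], edges$a[e])
    }
  }
  seen <- character(0)
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    stack <- n
    comp <- character(0)
    while (length(stack) > 0L) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      stack <- c(stack, setdiff(adj[[v]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps[order(vapply(comps, `[`, character(1L), 1L))]
}

## literal transcription of the Daura procedure executed by brute force on a
## precomputed pairwise RMSD matrix
oracle_daura <- function(rmat, cutoff) {
  nf <- nrow(rmat)
  remaining <- seq_len(nf)
  ids <- integer(nf)
  centers <- integer(0)
  cl <- 0L
  while (length(remaining) > 0L) {
    cl <- cl + 1L
    counts <- vapply(remaining, function(i)
      sum(rmat[i, remaining] <= cutoff), integer(1L))
    center <- remaining[which(counts == max(counts))[1L]]
    members <- remaining[rmat[center, remaining] <= cutoff]
    ids[members] <- cl
    centers[cl] <- center
    remaining <- setdiff(remaining, members)
  }
  list(ids = ids, centers = centers)
}

## random small structures/topologies for property tests ------------------

random_hbond_frame <- function(natoms_res = 10L, spread = 0.5) {
  ## ~5 atoms per residue (N,H,O + 2 others), compact so criteria fire often
  atoms <- do.call(rbind, lapply(seq_len(natoms_res), function(r) {
    data.frame(name = c("N", "H", "O", "CA", "CB"),
               element = c("N", "H", "O", "C", "C"),
               chain = if (r <= natoms_res / 2) "A" else "B",
               resid = ((r - 1L) %% (natoms_res %/% 2L)) + 1L,
               resname = "B3A",
               role = c("N", "H", "O", "CA", "CB"),
               stringsAsFactors = FALSE)
  }))
  xyz <- matrix(runif(nrow(atoms) * 3, 0, spread), ncol = 3L)
  ## put each H near its N so the donor-hydrogen criterion can pass
  for (r in which(atoms$role == "H"))
    xyz[r, ] <- xyz[r - 1L, ] + rnorm(3, 0, 0.05)
  list(atoms = atoms, xyz = xyz)
}

random_rigid_motion <- function(xyz) {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              nrow = 3L, byrow = TRUE)
  sweep(t(R %*% t(xyz)), 2L, rnorm(3), FUN = "+")
}

## tiny Trajectory directly from a list of coordinate matrices
traj_from_frames <- function(topo, frames, dt = 100) {
  co <- array(unlist(frames), dim = c(nrow(frames[[1L]]), 3L,
                                      length(frames)))
  new("Trajectory", topology = topo, coords = co,
      times = (seq_along(frames) - 1L) * dt,
      box = matrix(numeric(0), 0L, 3L))
}

## Partition constructed by hand for lifetime-tracking scenarios
hand_partition <- function(frame, classes) {
  structure(list(frame = frame, classes = classes), class = "Partition")
}
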