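test_that("built chains reproduce their input torsions (round trip)", {
  tor <- data.frame(phi = c(NA, -140, 70, -60, 150, -100),
                    theta = c(60, 55, -170, 80, -65, 40),
                    psi = c(-120, -135, 100, -80, 170, 30),
                    omega = c(NA, 180, 175, -178, 180, 179))
  tor$phi[1] <- 0; tor$omega[1] <- 0  # unused for residue 1
  conf <- buildBackbone(rep("B3A", 6), tor)
  m <- backboneTorsions(conf)
  for (r in 2:6) {
    expect_equal(wrapd(m$phi[r] - tor$phi[r]), 0, tolerance = 1e-3)
    expect_equal(wrapd(m$omega[r] - tor$omega[r]), 0, tolerance = 1e-3)
  }
  expect_equal(wrapd(m$theta - tor$theta), rep(0, 6), tolerance = 1e-3)
  expect_equal(wrapd(m$psi[1:5] - tor$psi[1:5]), rep(0, 5), tolerance = 1e-3)
  ## rebuild from measured torsions is idempotent
  m$phi[1] <- 0; m$omega[1] <- 0; m$psi[6] <- tor$psi[6]
  conf2 <- buildBackbone(rep("B3A", 6), m)
  expect_equal(coords(conf2), coords(conf), tolerance = 1e-9)
})

test_that("measured dihedrals agree with an independent atan2-free oracle", {
  conf <- buildBackbone(rep("B3A", 5), torsionPreset("helix314", 5))
  a <- atomData(conf)
  co <- coords(conf)
  at <- function(r, role) co[which(a$resid == r & a$role == role), ]
  m <- backboneTorsions(conf)
  for (r in 2:4) {
    expect_equal(m$phi[r],
                 oracle_dihedral(at(r - 1, "C"), at(r, "N"),
                                 at(r, "CB"), at(r, "CA")),
                 tolerance = 1e-9)
    expect_equal(m$theta[r],
                 oracle_dihedral(at(r, "N"), at(r, "CB"),
                                 at(r, "CA"), at(r, "C")),
                 tolerance = 1e-9)
  }
})

test_that("a 1-residue build yields exactly the template atoms", {
  conf <- buildBackbone("B3A", data.frame(phi = 0, theta = 60, psi = 0))
  expect_equal(atomData(conf)$name, c("N", "H", "CB", "CA", "C", "O"))
  expect_equal(nAtoms(conf), 6L)
})

test_that("unknown residue codes and torsion mismatches are rejected", {
  expect_error(buildBackbone("XXX", data.frame(phi = 0, theta = 0, psi = 0)),
               "template")
  expect_error(buildBackbone(rep("B3A", 3), torsionPreset("extended", 2)),
               "torsion")
})

test_that("the 14-helix preset forms its i -> i+2 hydrogen-bond ladder", {
  conf <- presetConformation("helix314", 6)
  a <- atomData(conf)
  co <- coords(conf)
  for (i in 1:4) {
    iH <- which(a$resid == i & a$role == "H")
    iO <- which(a$resid == i + 2 & a$role == "O")
    expect_lt(sqrt(sum((co[iH, ] - co[iO, ])^2)), 0.35)
  }
})

test_that("the 12-helix preset forms its i -> i-3 hydrogen-bond ladder", {
  conf <- presetConformation("helix2512", 6)
  a <- atomData(conf)
  co <- coords(conf)
  for (i in 4:6) {
    iH <- which(a$resid == i & a$role == "H")
    iO <- which(a$resid == i - 3 & a$role == "O")
    expect_lt(sqrt(sum((co[iH, ] - co[iO, ])^2)), 0.35)
  }
})

test_that("cyclic residues clamp theta to the ring value", {
  tor <- torsionPreset("extended", 4)
  conf <- buildBackbone(rep("ACH", 4), tor)
  m <- backboneTorsions(conf)
  expect_equal(m$theta, rep(55, 4), tolerance = 1e-3)
})

test_that("mirror-image torsions give mirror-image coordinates", {
  tor <- torsionPreset("helix314", 5)
  confL <- buildBackbone(rep("B3A", 5), tor)
  torR <- tor
  for (cc in c("phi", "theta", "psi", "omega")) torR[[cc]] <- -tor[[cc]]
  confR <- buildBackbone(rep("B3A", 5), torR)
  ## inverting the mirror image must superpose exactly onto the original
  inv <- -coords(confR)
  expect_lt(superpose(inv, coords(confL))$rmsd, 1e-9)
})

test_that("trajectory synthesis is deterministic and interpolates torsions", {
  start <- presetConformation("extended", 5)
  end <- presetConformation("helix314", 5)
  plan0 <- synthesisPlan(3, dt = 50, noiseSigma = 0, seed = 11)
  trj <- synthesizeTrajectory(start, end, plan0)
  expect_equal(nFrames(trj), 3L)
  expect_equal(frameTimes(trj), c(0, 50, 100))
  ## frame 0 equals the start, last frame the end
  expect_equal(trj@coords[, , 1], coords(start), tolerance = 1e-9)
  expect_equal(trj@coords[, , 3], coords(end), tolerance = 1e-9)
  ## midpoint frame torsions are halfway along the shortest angular path
  mid <- new("Conformation", topology = topology(start),
             coords = trj@coords[, , 2])
  mtor <- backboneTorsions(mid)
  t0 <- backboneTorsions(start)
  t1 <- backboneTorsions(end)
  for (r in 2:4) {
    expected <- t0$phi[r] + 0.5 * wrapd(t1$phi[r] - t0$phi[r])
    expect_equal(wrapd(mtor$phi[r]), wrapd(expected), tolerance = 1e-3)
  }
  ## identical seeds give identical trajectories, also with noise
  plan1 <- synthesisPlan(4, noiseSigma = 0.01, seed = 5)
  a1 <- synthesizeTrajectory(start, end, plan1)
  a2 <- synthesizeTrajectory(start, end, plan1)
  expect_identical(a1@coords, a2@coords)
  ## start == end, zero noise: all frames identical
  cst <- synthesizeTrajectory(start, start, synthesisPlan(4, noiseSigma = 0))
  for (k in 2:4) expect_equal(cst@coords[, , k], cst@coords[, , 1])
})

test_that("noise statistics match the requested sigma", {
  start <- presetConformation("helix314", 4)
  sigma <- 0.01
  trj <- synthesizeTrajectory(start, start,
                              synthesisPlan(1000, noiseSigma = sigma,
                                            seed = 42))
  disp <- sweep(trj@coords, c(1, 2), coords(start))
  expect_equal(sqrt(mean(disp^2)), sigma, tolerance = 0.05)
})

test_that("multichain assembly places proper-rotation copies on the grid", {
  conf <- presetConformation("helix314", 4)
  box <- assembleMultichain(conf, 8, spacing = 4, seed = 3)
  expect_equal(nAtoms(box), 8L * nAtoms(conf))
  expect_equal(length(chainIds(box)), 8L)
  ## determinism
  box2 <- assembleMultichain(conf, 8, spacing = 4, seed = 3)
  expect_identical(coords(box), coords(box2))
  ## each copy superposes exactly onto the template with a proper rotation
  a <- atomData(box)
  for (ch in chainIds(box)) {
    sub <- coords(box)[a$chain == ch, ]
    fit <- superpose(sub, coords(conf))
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
  ## chains do not sit on top of each other
  dmin <- min(dist(t(sapply(chainIds(box), function(ch)
    colMeans(coords(box)[a$chain == ch, ])))))
  expect_gt(dmin, 0)
  expect_error(assembleMultichain(conf, 6, spacing = 4), "cube")
})

test_that("the scripted association box produces interchain hydrogen bonds", {
  chain <- presetConformation("extended", 4)
  plan <- synthesisPlan(20, noiseSigma = 0.002, seed = 9)
  trj <- synthesizeAssociation(chain, 8, spacing = 3, plan)
  expect_equal(length(chainIds(trj)), 8L)
  sched <- defaultAssociationSchedule(20)
  mid <- sched$from[1] + 1L
  ev <- detectHBonds(trj, scope = "interchain", frames = mid)
  expect_gt(nrow(ev), 0)
  ## outside every window the box is bond-free
  ev0 <- detectHBonds(trj, scope = "interchain", frames = nFrames(trj))
  expect_equal(nrow(ev0), 0L)
})
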