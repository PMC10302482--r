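make_hbond_chain <- function(dists, nres = length(dists) + 2L) {
  ## synthetic single-chain topology whose H(i)...O(i+2) distances are set
  ## directly: atoms far apart except the controlled pairs
  atoms <- do.call(rbind, lapply(seq_len(nres), function(r)
    data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
               chain = "A", resid = r, resname = "B3A",
               role = c("N", "H", "O"), stringsAsFactors = FALSE)))
  xyz <- matrix(0, nrow(atoms), 3)
  for (r in seq_len(nres)) {
    base <- c(0, 0, 10 * r)
    xyz[(r - 1) * 3 + 1, ] <- base
    xyz[(r - 1) * 3 + 2, ] <- base + c(0.1, 0, 0)
    xyz[(r - 1) * 3 + 3, ] <- base + c(5, 0, 0)
  }
  for (i in seq_along(dists)) {
    ## move O(i+2) to the requested distance from H(i)
    xyz[(i + 1) * 3 + 3, ] <- xyz[(i - 1) * 3 + 2, ] + c(dists[i], 0, 0)
  }
  topo <- makeTopology(atoms)
  new("Trajectory", topology = topo,
      coords = array(xyz, dim = c(nrow(atoms), 3, 1)), times = 0,
      box = matrix(numeric(0), 0, 3))
}

test_that("helicity applies the switching score termwise over N-2 bonds", {
  ## every H(i)...O(i+2) at the 50% crossing -> score 0.5
  trj <- make_hbond_chain(rep(0.27, 4))
  expect_lt(abs(scoreValues(helicitySeries(trj)) - 0.5), 0.01)
  ## all broken -> essentially 0
  far <- make_hbond_chain(rep(5, 4))
  expect_lt(scoreValues(helicitySeries(far)), 1e-3)
  ## termwise oracle on mixed distances
  d <- c(0.15, 0.27, 0.44, 2)
  mix <- make_hbond_chain(d)
  expect_equal(scoreValues(helicitySeries(mix)),
               mean(switchingScore(d, switchingParams())), tolerance = 1e-12)
  ## N < 3 is undefined
  tiny <- make_hbond_chain(numeric(0), nres = 2L)
  expect_error(helicitySeries(tiny), "fewer than 3")
})

test_that("an ideal synthetic 14-helix scores >= 0.9 and extended <= 0.01", {
  hel <- presetConformation("helix314", 6)
  trj <- synthesizeTrajectory(hel, hel,
                              synthesisPlan(1000, noiseSigma = 0.005,
                                            seed = 1))
  s <- helicitySeries(trj)
  expect_true(all(scoreValues(s) >= 0 & scoreValues(s) <= 1))
  expect_gte(mean(scoreValues(s)), 0.9)
  ext <- presetConformation("extended", 6)
  trje <- synthesizeTrajectory(ext, ext,
                               synthesisPlan(200, noiseSigma = 0.005,
                                             seed = 2))
  expect_lte(mean(scoreValues(helicitySeries(trje))), 0.01)
})

test_that("scores are invariant under rigid-body motion of each frame", {
  hel <- presetConformation("helix314", 6)
  trj <- synthesizeTrajectory(hel, hel,
                              synthesisPlan(5, noiseSigma = 0.01, seed = 8))
  set.seed(99)
  moved <- trj
  for (k in 1:5) moved@coords[, , k] <- random_rigid_motion(trj@coords[, , k])
  expect_equal(scoreValues(helicitySeries(moved)),
               scoreValues(helicitySeries(trj)), tolerance = 1e-9)
  expect_equal(scoreValues(hairpinSeries(moved)),
               scoreValues(hairpinSeries(trj)), tolerance = 1e-9)
})

test_that("hairpin score averages the designated bonds only", {
  ## chain with controllable H(i)...O(j): reuse the helix fixture and pick
  ## designated pairs (1,3), (2,4), (3,5) == the i -> i+2 ladder
  d <- c(0.27, 5, 5)
  trj <- make_hbond_chain(c(d, 5))
  spec <- hairpinSpec(cbind(donor = c(1, 2, 3), acceptor = c(3, 4, 5)))
  got <- scoreValues(hairpinSeries(trj, spec))
  ## exactly one of three bonds at the 50% anchor -> 0.5 / 3 (the broken
  ## bonds at 5 nm still contribute their ~1e-6 switching tail)
  expect_equal(got, mean(switchingScore(c(0.27, 5, 5))), tolerance = 1e-12)
  expect_lt(abs(got - 0.5 / 3), 0.01)
  ## permuting the designated pairs leaves the score unchanged
  sp2 <- hairpinSpec(cbind(donor = c(3, 1, 2), acceptor = c(5, 3, 4)))
  expect_equal(scoreValues(hairpinSeries(trj, sp2)), got)
  ## referencing absent residues is an error
  bad <- hairpinSpec(cbind(donor = 1, acceptor = 99))
  expect_error(hairpinSeries(trj, bad), "absent")
})

test_that("the ideal hairpin fixture scores >= 0.9 on its three bonds", {
  hp <- buildBackbone(rep("B3A", 6), torsionPreset("hairpin", 6))
  trj <- synthesizeTrajectory(hp, hp,
                              synthesisPlan(100, noiseSigma = 0.005,
                                            seed = 5))
  expect_gte(mean(scoreValues(hairpinSeries(trj))), 0.9)
})

test_that("NOE effective distances follow the r^-6 closed forms", {
  atoms <- data.frame(name = c("HA", "HB"), element = "H", chain = "A",
                      resid = c(1L, 2L), resname = "B3A", role = "other",
                      stringsAsFactors = FALSE)
  topo <- makeTopology(atoms)
  mk <- function(dists) {
    frames <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
    traj_from_frames(topo, frames, dt = 1)
  }
  rest <- data.frame(chain_i = "A", resid_i = 1L, atom_names_i = "HA",
                     chain_j = "A", resid_j = 2L, atom_names_j = "HB",
                     r_exp_nm = 0.25, stringsAsFactors = FALSE)
  ## constant series: violation is exactly r - r_exp
  v <- noeViolations(mk(rep(0.30, 4)), rest, window = c(0, 3))
  expect_equal(v$r_eff_nm, 0.30, tolerance = 1e-12)
  expect_equal(v$violation_nm, 0.05, tolerance = 1e-12)
  expect_true(v$positive)
  ## two-frame closed form
  v2 <- noeViolations(mk(c(0.2, 0.4)), rest, window = c(0, 1))
  expect_equal(v2$r_eff_nm, ((0.2^-6 + 0.4^-6) / 2)^(-1 / 6),
               tolerance = 1e-12)
  ## r^-6 averaging never exceeds the arithmetic mean; equality iff constant
  expect_lt(v2$r_eff_nm, mean(c(0.2, 0.4)))
  ## negative violations are flagged non-positive
  v3 <- noeViolations(mk(rep(0.2, 2)), rest, window = c(0, 1))
  expect_false(v3$positive)
  expect_error(noeViolations(mk(rep(0.3, 2)), rest, window = c(50, 60)),
               "window")
})

test_that("equivalence groups use the per-frame minimum distance", {
  atoms <- data.frame(name = c("HA1", "HA2", "HB"), element = "H",
                      chain = "A", resid = c(1L, 1L, 2L), resname = "B3A",
                      role = "other", stringsAsFactors = FALSE)
  topo <- makeTopology(atoms)
  fr <- rbind(c(0.3, 0, 0), c(0.5, 0, 0), c(0, 0, 0))
  trj <- traj_from_frames(topo, list(fr), dt = 1)
  rest <- data.frame(chain_i = "A", resid_i = 1L, atom_names_i = "HA1|HA2",
                     chain_j = "A", resid_j = 2L, atom_names_j = "HB",
                     r_exp_nm = 0.25, stringsAsFactors = FALSE)
  v <- noeViolations(trj, rest, window = c(0, 0))
  expect_equal(v$r_eff_nm, 0.3, tolerance = 1e-12)
  ## the default averaging window is the final 60% of frames
  trj10 <- traj_from_frames(topo, rep(list(fr), 10), dt = 1)
  v10 <- noeViolations(trj10, rest)
  expect_equal(v10$window_start_ps, 4)
  expect_equal(v10$window_end_ps, 9)
})

test_that("score series export and density summaries work", {
  hel <- presetConformation("helix314", 6)
  trj <- synthesizeTrajectory(hel, hel, synthesisPlan(20, noiseSigma = 0.005,
                                                      seed = 3))
  s <- helicitySeries(trj)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeScoreCSV(s, tmp)
  back <- read.csv(tmp)
  expect_equal(back$time_ps, frameTimes(s))
  expect_equal(back$score, scoreValues(s))
  dd <- scoreDensity(s)
  expect_s3_class(dd, "density")
})
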