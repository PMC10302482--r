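## helper: trajectory of `nch` single-atom-per-role chains whose interchain
## bonds are scripted per frame as a list of chain-pair edges
scripted_traj <- function(nch, frame_edges) {
  chains <- LETTERS[seq_len(nch)]
  atoms <- do.call(rbind, lapply(chains, function(ch)
    data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
               chain = ch, resid = 1L, resname = "B3A",
               role = c("N", "H", "O"), stringsAsFactors = FALSE)))
  base <- matrix(0, nrow(atoms), 3)
  for (i in seq_len(nch)) {
    off <- c(0, 0, 10 * i)
    base[(i - 1) * 3 + 1, ] <- off
    base[(i - 1) * 3 + 2, ] <- off + c(0.1, 0, 0)
    base[(i - 1) * 3 + 3, ] <- off + c(5, 0, 0)
  }
  frames <- lapply(frame_edges, function(edges) {
    xyz <- base
    if (length(edges) > 0) {
      for (e in edges) {
        ## donor chain e[1] hydrogen bonds acceptor chain e[2]: put the
        ## acceptor O collinearly 0.19 nm beyond the donor H
        i <- match(e[1], chains)
        j <- match(e[2], chains)
        xyz[(j - 1) * 3 + 3, ] <- xyz[(i - 1) * 3 + 2, ] + c(0.19, 0, 0)
      }
    }
    xyz
  })
  traj_from_frames(makeTopology(atoms), frames, dt = 100)
}

test_that("interchain graphs contain exactly the bonded chain pairs", {
  trj <- scripted_traj(4, list(list(), list(c("A", "B")),
                               list(c("A", "B"), c("B", "C"))))
  g1 <- interchainGraph(trj, 1)
  expect_equal(nrow(g1$edges), 0L)
  g2 <- interchainGraph(trj, 2)
  expect_equal(g2$edges, data.frame(a = "A", b = "B",
                                    stringsAsFactors = FALSE))
  g3 <- interchainGraph(trj, 3)
  expect_equal(nrow(g3$edges), 2L)
  ## direction is ignored: a bond donated B -> A gives the same edge
  rev <- scripted_traj(2, list(list(c("B", "A"))))
  expect_equal(interchainGraph(rev, 1)$edges$a, "A")
  ## single-chain topologies are rejected
  one <- scripted_traj(2, list(list()))
  one@topology@atoms <- one@topology@atoms[1:3, ]
  one@coords <- one@coords[1:3, , , drop = FALSE]
  expect_error(interchainGraph(one, 1), "two chains")
})

test_that("Hoshen-Kopelman labeling equals DFS components on random graphs", {
  set.seed(123)
  for (rep in 1:1000) {
    n <- sample(2:8, 1)
    nodes <- LETTERS[seq_len(n)]
    npairs <- n * (n - 1) / 2
    pick <- runif(npairs) < 0.3
    all_pairs <- t(combn(nodes, 2))
    edges <- data.frame(a = all_pairs[pick, 1], b = all_pairs[pick, 2],
                        stringsAsFactors = FALSE)
    part <- labelClusters(list(frame = 1L, nodes = nodes, edges = edges))
    want <- oracle_components(nodes, edges)
    expect_equal(part$classes, want)
  }
  ## classes partition the chain set
  g <- list(frame = 1L, nodes = LETTERS[1:8],
            edges = data.frame(a = c("A", "B"), b = c("B", "C"),
                               stringsAsFactors = FALSE))
  p <- labelClusters(g)
  expect_setequal(unlist(p$classes), LETTERS[1:8])
  expect_equal(sum(lengths(p$classes)), 8L)
  expect_equal(p$classes[[1]], c("A", "B", "C"))
})

test_that("a nested trimer keeps the underlying dimer alive", {
  ## AB bonded frames 1-10; C attached frames 5-7 (1-based frames)
  cls <- function(f) {
    if (f >= 5 && f <= 7) list(c("A", "B", "C"), "D")
    else list(c("A", "B"), "C", "D")
  }
  parts <- lapply(1:10, function(f) hand_partition(f, cls(f)))
  ev <- trackAssociates(parts, times = (0:9) * 100)
  dimer <- ev[ev$order == 2, ]
  trimer <- ev[ev$order == 3, ]
  expect_equal(nrow(dimer), 1L)
  expect_equal(nrow(trimer), 1L)
  ## dimer spans all 10 frames, alive inside the trimer
  expect_equal(dimer$n_frames, 10L)
  expect_equal(dimer$birth_frame, 1L)
  expect_equal(dimer$death_frame, 10L)
  expect_true(dimer$open)
  ## trimer spans exactly frames 5-7
  expect_equal(trimer$n_frames, 3L)
  expect_equal(trimer$birth_frame, 5L)
  expect_equal(trimer$death_frame, 7L)
  expect_false(trimer$open)
})

test_that("splits follow the larger-overlap successor", {
  parts <- list(
    hand_partition(1, list(c("A", "B", "C"), "D")),
    hand_partition(2, list(c("A", "B"), "C", "D")),
    hand_partition(3, list(c("A", "B"), "C", "D")))
  ev <- trackAssociates(parts, times = 0:2)
  ## one lineage: trimer dies after frame 1, dimer continues to the end
  expect_equal(sort(unique(ev$lineage)), 1L)
  tri <- ev[ev$order == 3, ]
  dim2 <- ev[ev$order == 2, ]
  expect_equal(tri$death_frame, 1L)
  expect_equal(dim2$n_frames, 3L)
  expect_true(dim2$open)
})

test_that("dissolution kills events and reformation starts a new lineage", {
  parts <- list(
    hand_partition(1, list(c("A", "B"), "C")),
    hand_partition(2, list("A", "B", "C")),
    hand_partition(3, list(c("A", "B"), "C")))
  ev <- trackAssociates(parts, times = 0:2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_frames, c(1L, 1L))
  expect_equal(sort(ev$lineage), c(1L, 2L))
  ## with gap = 1 the single missing frame is bridged into one event
  ev_gap <- trackAssociates(parts, times = 0:2, gap = 1L)
  expect_equal(nrow(ev_gap), 1L)
  expect_equal(ev_gap$birth_frame, 1L)
  expect_equal(ev_gap$death_frame, 3L)
})

test_that("de novo larger associates open all sub-orders at once", {
  parts <- list(
    hand_partition(1, list("A", "B", "C")),
    hand_partition(2, list(c("A", "B", "C"))),
    hand_partition(3, list(c("A", "B", "C"))))
  ev <- trackAssociates(parts, times = 0:2)
  expect_setequal(ev$order, 2:3)
  expect_equal(ev$birth_frame, c(2L, 2L))
  ## nesting property: frames alive for order k+1 are a subset of order k
  expect_lte(ev$n_frames[ev$order == 3], ev$n_frames[ev$order == 2])
})

test_that("lifetime statistics match hand arithmetic", {
  ## single 5 ns event in a 100 ns run sampled at 0.1 ns
  ev <- data.frame(lineage = 1L, order = 2L, birth_frame = 11L,
                   death_frame = 60L, birth_ps = 1000, death_ps = 5900,
                   n_frames = 50L, open = FALSE, members = "A+B")
  tab <- lifetimeStatistics(ev, spanPs = 1e5, dtPs = 100)
  expect_equal(tab$median_lifetime_ns, 5)
  expect_equal(tab$longest_lifetime_ns, 5)
  expect_equal(tab$trajectory_percent, 5)
  expect_equal(tab$per_1000ns, 10)
  ## order statistics over 1, 2, 9 ns events
  ev3 <- do.call(rbind, lapply(seq_len(3), function(i) {
    nfr <- c(10L, 20L, 90L)[i]
    data.frame(lineage = i, order = 2L, birth_frame = 1L + 100L * (i - 1L),
               death_frame = 100L * (i - 1L) + nfr,
               birth_ps = 0, death_ps = 0, n_frames = nfr, open = FALSE,
               members = "A+B")
  }))
  tab3 <- lifetimeStatistics(ev3, spanPs = 1e5, dtPs = 100)
  expect_equal(tab3$median_lifetime_ns, 2)
  expect_equal(tab3$longest_lifetime_ns, 9)
  expect_equal(tab3$n_events, 3L)
  ## absent orders yield no row
  expect_false(3 %in% tab3$order)
})

test_that("statistics are invariant to chain relabeling", {
  edges_by_frame <- list(list(c("A", "B")), list(c("A", "B"), c("B", "C")),
                         list(c("B", "C")), list())
  trj <- scripted_traj(4, edges_by_frame)
  ev <- associateEvents(trj)
  ## relabel chains by reversing the alphabet
  relab <- rev(LETTERS[1:4])[match(atomData(trj)$chain, LETTERS[1:4])]
  trj2 <- trj
  trj2@topology@atoms$chain <- relab
  ev2 <- associateEvents(trj2)
  s1 <- lifetimeStatistics(ev, 400, 100)
  s2 <- lifetimeStatistics(ev2, 400, 100)
  expect_equal(s1, s2)
})

test_that("the end-to-end association pipeline finds scripted oligomers", {
  chain <- presetConformation("extended", 4)
  plan <- synthesisPlan(40, dt = 100, noiseSigma = 0.002, seed = 2)
  trj <- synthesizeAssociation(chain, 8, spacing = 3, plan)
  ev <- associateEvents(trj)
  expect_true(2L %in% ev$order)
  expect_true(3L %in% ev$order)
  tab <- lifetimeStatistics(ev, spanPs = nFrames(trj) * 100, dtPs = 100)
  expect_true(all(tab$longest_lifetime_ns >= tab$median_lifetime_ns))
  expect_true(all(tab$trajectory_percent >= 0 &
                    tab$trajectory_percent <= 100))
  ## the dimer hosting the trimer outlives it (sub-associate rule)
  d <- tab[tab$order == 2, ]
  t3 <- tab[tab$order == 3, ]
  expect_gte(d$longest_lifetime_ns, t3$longest_lifetime_ns)
})
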