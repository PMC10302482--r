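## Multichain associate analytics: interchain hydrogen-bond graphs,
## Hoshen-Kopelman cluster labeling, lifetime event tracking with the
## sub-associate rule, and summary statistics.

#' Interchain hydrogen-bond contact graph of one frame
#'
#' Chains are nodes; an edge joins two chains linked by at least one
#' interchain hydrogen bond (discrete criterion), in either direction.
#'
#' @param x a \linkS4class{Trajectory}.
#' @param frame frame index.
#' @param criteria an \linkS4class{HBondCriteria} object.
#' @return list with elements `frame`, `nodes` (chain ids) and `edges`
#'   (two-column data.frame of chain pairs, a < b).
#' @export
interchainGraph <- function(x, frame = 1L, criteria = hbondCriteria()) {
  nodes <- chainIds(x)
  if (length(nodes) < 2L)
    stopf("interchain analysis needs at least two chains")
  ev <- detectHBonds(x, criteria, scope = "interchain", frames = frame)
  edges <- if (nrow(ev) == 0L) {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  } else {
    pr <- unique(data.frame(
      a = pmin(ev$donorChain, ev$acceptorChain),
      b = pmax(ev$donorChain, ev$acceptorChain),
      stringsAsFactors = FALSE))
    rownames(pr) <- NULL
    pr
  }
  list(frame = frame, nodes = nodes, edges = edges)
}

#' Hoshen-Kopelman labeling of a contact graph
#'
#' Sorts the chains into equivalence classes (connected components of the
#' hydrogen-bond contact graph) with union-find label merging; classes are
#' canonicalized by their smallest member chain id.
#'
#' @param graph a contact graph as from \code{\link{interchainGraph}}, or any
#'   list with `nodes` and `edges` in that shape.
#' @return list of class `Partition` with elements `frame` and `classes`
#'   (list of character vectors, each sorted, ordered by smallest member).
#' @export
labelClusters <- function(graph) {
  nodes <- graph$nodes
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(graph$edges) > 0L) {
    for (e in seq_len(nrow(graph$edges))) {
      i <- find(match(graph$edges$a[e], nodes))
      j <- find(match(graph$edges$b[e], nodes))
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  root <- vapply(seq_along(nodes), find, integer(1L))
  classes <- split(nodes, root)
  classes <- lapply(classes, sort)
  classes <- classes[order(vapply(classes, `[`, character(1L), 1L))]
  names(classes) <- NULL
  structure(list(frame = graph$frame, classes = classes),
            class = "Partition")
}

#' Track associate lifetimes through a sequence of partitions
#'
#' Components of two or more chains are matched frame-to-frame into lineages
#' by maximal member overlap (ties broken toward the smallest chain id).
#' Within a lineage an order-k associate event (dimer k = 2, trimer k = 3,
#' ...) is alive while the lineage has at least k members: the underlying
#' smaller associate is treated as alive while being part of a larger one. An
#' event is born when the lineage first reaches size k and dies when the size
#' drops below k (or the lineage dissolves); a component appearing de novo
#' with s > 2 members opens events for every order 2..s at once. A single
#' frame of disconnection ends a lineage unless `gap` allows bridging.
#'
#' @param partitions list of `Partition` objects (see
#'   \code{\link{labelClusters}}) in time order.
#' @param times frame times in ps, one per partition.
#' @param gap number of consecutive absent frames a lineage may survive
#'   (default 0: none).
#' @return data.frame of events: `lineage`, `order`, `birth_frame`,
#'   `death_frame` (indices into `partitions`), `birth_ps`, `death_ps`,
#'   `n_frames` alive, `open` (TRUE when still alive at the final frame),
#'   `members` (chain set at birth, "+"-separated).
#' @export
trackAssociates <- function(partitions, times = seq_along(partitions),
                            gap = 0L) {
  if (length(times) != length(partitions))
    stopf("need one time per partition")
  if (length(times) > 1L && any(diff(times) <= 0))
    stopf("partition times must be strictly increasing")
  lineages <- list()   # id -> list(members, events = list(order -> birth), missed)
  next_id <- 1L
  done <- list()

  close_event <- function(id, order, death_frame) {
    li <- lineages[[as.character(id)]]
    done[[length(done) + 1L]] <<- data.frame(
      lineage = id, order = order,
      birth_frame = li$events[[as.character(order)]]$frame,
      death_frame = death_frame,
      members = li$events[[as.character(order)]]$members,
      open = FALSE, stringsAsFactors = FALSE)
  }

  min_id <- function(members) sort(members)[1L]

  for (t in seq_along(partitions)) {
    comps <- Filter(function(cl) length(cl) >= 2L, partitions[[t]]$classes)
    lids <- names(lineages)
    ## overlap matrix lineages x comps
    if (length(lids) > 0L && length(comps) > 0L) {
      ov <- matrix(0L, length(lids), length(comps))
      for (i in seq_along(lids))
        for (j in seq_along(comps))
          ov[i, j] <- length(intersect(lineages[[lids[i]]]$members,
                                       comps[[j]]))
    } else {
      ov <- matrix(0L, length(lids), length(comps))
    }
    matched_l <- character(0)
    matched_c <- integer(0)
    while (length(ov) > 0L && max(ov) > 0L) {
      mx <- max(ov)
      cand <- which(ov == mx, arr.ind = TRUE)
      ## deterministic tie-break: smallest chain id of the lineage, then of
      ## the component
      ord <- order(vapply(cand[, 1L], function(i)
                     min_id(lineages[[lids[i]]]$members), character(1L)),
                   vapply(cand[, 2L], function(j) min_id(comps[[j]]),
                          character(1L)))
      pick <- cand[ord[1L], ]
      i <- pick[[1L]]; j <- pick[[2L]]
      lid <- lids[i]
      matched_l <- c(matched_l, lid)
      matched_c <- c(matched_c, j)
      ov[i, ] <- 0L
      ov[, j] <- 0L
      ## update lineage with the successor component
      li <- lineages[[lid]]
      li$members <- comps[[j]]
      li$missed <- 0L
      s <- length(comps[[j]])
      for (k in names(li$events)) {
        if (as.integer(k) > s) {
          lineages[[lid]] <- li
          close_event(as.integer(lid), as.integer(k), t - 1L)
          li$events[[k]] <- NULL
        }
      }
      for (k in 2:s) {
        if (is.null(li$events[[as.character(k)]]))
          li$events[[as.character(k)]] <-
            list(frame = t, members = paste(sort(comps[[j]]), collapse = "+"))
      }
      lineages[[lid]] <- li
    }
    ## unmatched lineages: allow `gap` missed frames, then dissolve
    for (lid in setdiff(lids, matched_l)) {
      li <- lineages[[lid]]
      li$missed <- li$missed + 1L
      if (li$missed > gap) {
        for (k in names(li$events))
          close_event(as.integer(lid), as.integer(k), t - li$missed)
        lineages[[lid]] <- NULL
      } else {
        lineages[[lid]] <- li
      }
    }
    ## unmatched components: new lineages, events for all orders at once
    for (j in setdiff(seq_along(comps), matched_c)) {
      s <- length(comps[[j]])
      ev <- list()
      for (k in 2:s)
        ev[[as.character(k)]] <-
          list(frame = t, members = paste(sort(comps[[j]]), collapse = "+"))
      lineages[[as.character(next_id)]] <-
        list(members = comps[[j]], events = ev, missed = 0L)
      next_id <- next_id + 1L
    }
  }
  ## events open at the end: right-censored, flagged
  nlast <- length(partitions)
  for (lid in names(lineages)) {
    li <- lineages[[lid]]
    for (k in names(li$events)) {
      done[[length(done) + 1L]] <- data.frame(
        lineage = as.integer(lid), order = as.integer(k),
        birth_frame = li$events[[k]]$frame,
        death_frame = nlast - li$missed,
        members = li$events[[k]]$members,
        open = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(done) == 0L)
    return(data.frame(lineage = integer(0), order = integer(0),
                      birth_frame = integer(0), death_frame = integer(0),
                      birth_ps = numeric(0), death_ps = numeric(0),
                      n_frames = integer(0), open = logical(0),
                      members = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, done)
  out$birth_ps <- times[out$birth_frame]
  out$death_ps <- times[out$death_frame]
  out$n_frames <- out$death_frame - out$birth_frame + 1L
  out <- out[order(out$lineage, out$order), c(
    "lineage", "order", "birth_frame", "death_frame", "birth_ps",
    "death_ps", "n_frames", "open", "members")]
  rownames(out) <- NULL
  out
}

#' Detect and track associates over a whole trajectory
#'
#' Convenience wrapper: builds the interchain contact graph of every frame,
#' labels the clusters and tracks the lifetimes.
#'
#' @param traj a multichain \linkS4class{Trajectory}.
#' @param criteria an \linkS4class{HBondCriteria} object.
#' @param gap see \code{\link{trackAssociates}}.
#' @return data.frame of events, see \code{\link{trackAssociates}}.
#' @export
associateEvents <- function(traj, criteria = hbondCriteria(), gap = 0L) {
  parts <- lapply(seq_len(nFrames(traj)), function(k)
    labelClusters(interchainGraph(traj, k, criteria)))
  trackAssociates(parts, frameTimes(traj), gap = gap)
}

#' Lifetime summary statistics of associate events
#'
#' Per associate order k the table reports the median and longest event
#' lifetime (ns, counting each alive frame as one dt interval), the
#' percentage of trajectory frames in which at least one order-k associate is
#' alive, and the number of events normalized to 1000 ns. Orders with no
#' events are absent from the table. Events open at the end of the trajectory
#' enter with their observed (right-censored) length.
#'
#' @param events data.frame from \code{\link{trackAssociates}}.
#' @param spanPs trajectory span in ps (frame count times dt).
#' @param dtPs frame interval in ps.
#' @return data.frame with columns `order`, `n_events`,
#'   `median_lifetime_ns`, `longest_lifetime_ns`, `trajectory_percent`,
#'   `per_1000ns`.
#' @export
lifetimeStatistics <- function(events, spanPs, dtPs) {
  if (spanPs <= 0) stopf("trajectory span must be positive")
  n_frames_total <- round(spanPs / dtPs)
  span_ns <- spanPs / 1000
  orders <- sort(unique(events$order))
  out <- lapply(orders, function(k) {
    ev <- events[events$order == k, , drop = FALSE]
    life_ns <- ev$n_frames * dtPs / 1000
    alive <- unique(unlist(mapply(seq, ev$birth_frame, ev$death_frame,
                                  SIMPLIFY = FALSE)))
    data.frame(order = k, n_events = nrow(ev),
               median_lifetime_ns = stats::median(life_ns),
               longest_lifetime_ns = max(life_ns),
               trajectory_percent = 100 * length(alive) / n_frames_total,
               per_1000ns = nrow(ev) * 1000 / span_ns)
  })
  if (length(out) == 0L)
    return(data.frame(order = integer(0), n_events = integer(0),
                      median_lifetime_ns = numeric(0),
                      longest_lifetime_ns = numeric(0),
                      trajectory_percent = numeric(0),
                      per_1000ns = numeric(0)))
  do.call(rbind, out)
}
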