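test_that("basins retain the orbits of goal states and exclude costly ones", {
  ## chain 1 -> 2 -> 3, goal {2}: everything is in an orbit
  b <- array(0, c(3, 3, 1))
  b[2, 1, 1] <- 1; b[3, 2, 1] <- 1
  r <- basins(b, goal_spec(c(F, T, F), t_max = 32L))
  expect_identical(r$retained, rep(TRUE, 3))
  ## costly state 3 is excluded along with transitions into it
  r2 <- basins(b, goal_spec(c(F, T, F), chi = c(F, F, T), t_max = 32L))
  expect_identical(r2$retained, c(TRUE, TRUE, FALSE))
  expect_identical(dim(r2$R), c(3L, 2L))
  ## oracle equivalence on random digraphs: union of BFS ancestors and
  ## descendants of the goals within the horizon, excluding costly states
  for (sd in 1:100) {
    n <- sample(10:30, 1)
    b3 <- random_digraph_b(n = n, p = 0.1, seed = 700 + sd)
    gamma <- rep(FALSE, n); gamma[sample(n, 2)] <- TRUE
    chi <- rep(FALSE, n); chi[sample(which(!gamma), 2)] <- TRUE
    gs <- goal_spec(gamma, chi, t_max = 32L)
    got <- basins(b3, gs)$retained
    adjm <- apply(b3, c(1, 2), sum) > 0
    adjm[which(chi), ] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(t(adjm * 1), mode = "directed")
    danc <- suppressWarnings(apply(igraph::distances(g, to = which(gs$gamma),
                                                     mode = "out"), 1, min))
    ddes <- suppressWarnings(apply(igraph::distances(g, v = which(gs$gamma),
                                                     mode = "out"), 2, min))
    oracle <- !chi & (gs$gamma | (danc <= 32) | (ddes <= 32))
    expect_identical(got, unname(oracle))
  }
})

test_that("tensor slicing drops exactly the removed states", {
  b <- random_digraph_b(n = 6L, p = 0.4, seed = 1)
  a <- list(matrix(rpois(18, 2), 3, 6))
  keep <- rep(TRUE, 6)
  same <- reduce_tensors(b, a, keep)
  expect_equal(same$b, b[, , apply(b, 3, sum) > 0, drop = FALSE])
  expect_equal(same$a[[1]], a[[1]])
  keep[4] <- FALSE
  red <- reduce_tensors(b, a, keep)
  expect_identical(dim(red$b)[1:2], c(5L, 5L))
  expect_identical(ncol(red$a[[1]]), 5L)
  ## reducing twice composes like reducing once by the conjunction
  keep2 <- rep(TRUE, 5); keep2[2] <- FALSE
  twice <- reduce_tensors(red$b, red$a, keep2)
  keep12 <- keep; keep12[which(keep)[2]] <- FALSE
  once <- reduce_tensors(b, a, keep12)
  expect_equal(twice$a[[1]], once$a[[1]])
})

test_that("model reduction drops exactly the deselected states", {
  p <- fixture_pipeline()
  m <- p$m2
  ## a null reduction changes nothing
  same <- reduce_model(m, rep(TRUE, m$top$n_states))
  expect_identical(sum(same$top$active), sum(m$top$active))
  expect_identical(same$top$tr$count, m$top$tr$count)
  ## dropping one active state removes it and its transitions, and no
  ## retained transition references it afterwards
  victim <- which(m$top$active)[5L]
  keep <- rep(TRUE, m$top$n_states); keep[victim] <- FALSE
  red <- reduce_model(m, keep)
  expect_false(red$top$active[victim])
  expect_false(victim %in% red$top$tr$from)
  expect_false(victim %in% red$top$tr$to)
  ## path slots stay contiguous per source
  for (s in unique(red$top$tr$from)[1:10])
    expect_identical(sort(red$top$tr$slot[red$top$tr$from == s]),
                     seq_len(sum(red$top$tr$from == s)))
  ## composing two reductions equals the single conjunction
  keep2 <- keep; keep2[which(m$top$active)[8L]] <- FALSE
  once <- reduce_model(m, keep2)
  twice <- reduce_model(red, keep2)
  expect_identical(once$top$active, twice$top$active)
  expect_identical(sort(once$top$tr$keys), sort(twice$top$tr$keys))
})

test_that("the goal core is the strongly connected goal set", {
  ## a goal cycle is entirely on the attractor
  b <- array(0, c(3, 3, 1))
  b[2, 1, 1] <- 1; b[3, 2, 1] <- 1; b[1, 3, 1] <- 1
  core <- attractor_goal_set(b, goal_spec(rep(TRUE, 3), t_max = 32L))
  expect_identical(core, rep(TRUE, 3))
  ## a goal with successors but no predecessors is off the attractor
  b2 <- array(0, c(4, 4, 1))
  b2[2, 1, 1] <- 1; b2[3, 2, 1] <- 1; b2[2, 3, 1] <- 1
  core2 <- attractor_goal_set(b2, goal_spec(c(T, T, T, F), t_max = 32L))
  expect_identical(core2, c(FALSE, TRUE, TRUE, FALSE))
  ## oracle: intersection of the goal set with strongly connected components
  for (sd in 1:40) {
    n <- sample(10:25, 1)
    b3 <- random_digraph_b(n = n, p = 0.12, seed = 900 + sd)
    gamma <- rep(FALSE, n); gamma[sample(n, 4)] <- TRUE
    gs <- goal_spec(gamma, t_max = n)     # horizon covers the whole graph
    got <- attractor_goal_set(b3, gs)
    adjm <- apply(b3, c(1, 2), sum) > 0
    g <- igraph::graph_from_adjacency_matrix(t(adjm * 1), mode = "directed")
    comp <- igraph::components(g, mode = "strong")
    sizes <- tabulate(comp$membership, comp$no)
    oracle <- gamma & sizes[comp$membership] >= 2
    ## goals in non-trivial SCCs must be in the core (the core may add
    ## self-loop goals, absent here by construction)
    expect_true(all(got[oracle]))
    expect_true(all(gamma[got]))
  }
})

test_that("dead-end pruning reaches the sink-free fixed point", {
  ## cycle {1,2} with a terminal appendage 3
  m <- matrix(FALSE, 3, 3)
  m[2, 1] <- m[1, 2] <- m[3, 2] <- TRUE
  pr <- prune_dead_ends(m)
  expect_identical(pr$retained, c(TRUE, TRUE, FALSE))
  ## an acyclic chain cascades away entirely
  chain <- matrix(FALSE, 3, 3); chain[2, 1] <- chain[3, 2] <- TRUE
  expect_error(prune_dead_ends(chain), "pruned")
  ## oracle: iterative sink deletion
  for (sd in 1:40) {
    n <- sample(8:20, 1)
    set.seed(1100 + sd)
    a <- matrix(runif(n * n) < 0.15, n, n); diag(a) <- FALSE
    ok <- tryCatch(prune_dead_ends(a), error = function(e) NULL)
    keep <- rep(TRUE, n); mm <- a
    repeat {
      s <- keep & colSums(mm) == 0
      if (!any(s)) break
      keep[s] <- FALSE; mm[, s] <- FALSE; mm[s, ] <- FALSE
    }
    if (is.null(ok)) expect_false(any(keep)) else
      expect_identical(ok$retained, keep)
  }
})

test_that("transitive reduction preserves the transitive closure", {
  a <- matrix(FALSE, 3, 3)
  a[2, 1] <- a[3, 2] <- a[3, 1] <- TRUE   # 1->2, 2->3, 1->3
  red <- transitive_reduction(a)
  expect_identical(red, matrix(c(F, T, F, F, F, T, F, F, F), 3, 3))
  closure <- function(m) {
    c0 <- m
    repeat { nxt <- (c0 %*% c0 + c0) > 0; if (identical(nxt, c0)) break; c0 <- nxt }
    c0
  }
  for (sd in 1:30) {
    n <- sample(5:12, 1)
    set.seed(1300 + sd)
    a2 <- matrix(runif(n * n) < 0.25, n, n)
    a2[upper.tri(a2, diag = TRUE)] <- FALSE   # random DAG
    r2 <- transitive_reduction(a2)
    expect_identical(closure(r2 * 1 > 0), closure(a2))
    expect_lte(sum(r2), sum(a2))
  }
})

test_that("attractor learning discovers a large mutually reachable goal core", {
  p <- fixture_pipeline()
  m2 <- p$m2
  expect_true(m2$attractor_converged)
  gs <- mark_goal_cost_states(m2)
  expect_gte(sum(gs$gamma), p$cfg$goal_threshold)
  ## the attractor never contains a costly state
  expect_identical(sum(m2$top$cost & m2$top$active), 0L)
  ## after pruning every retained state has at least one successor
  od <- denovolearn:::.active_outdeg(m2)
  expect_true(all(od[m2$top$active] >= 1L))
  ## the goal core is strongly connected within the horizon (oracle check
  ## via pairwise reachability on the reduced graph)
  core <- denovolearn:::.goal_core_model(m2, p$cfg$basin_horizon)
  expect_gte(sum(core), p$cfg$goal_threshold)
  adj <- denovolearn:::.top_adj(m2, exclude_cost = TRUE)
  cid <- which(core)
  probe <- cid[seq(1L, length(cid), length.out = min(8L, length(cid)))]
  for (s in probe) {
    d <- denovolearn:::.bfs_dist(adj$out, s, 20L * p$cfg$basin_horizon)
    expect_true(all(is.finite(d[setdiff(cid, s)])))
  }
})

test_that("an environment that never rewards blocks all assimilation", {
  cfg <- denovo_config(game = game_config(central_cols = integer(0)),
                       frames = 600L, epoch_budget = 10L, seed = 2L)
  r <- play_frames(new_game(cfg$game, seed = cfg$seed), cfg$frames, "random")
  m1 <- learn_structure(r$obs, cfg)
  m2 <- learn_attractor(m1, cfg)
  expect_false(m2$attractor_converged)
  expect_identical(nrow(m2$history$attractor), 0L)
  expect_identical(m2$top$n_states, 0L)
})

test_that("a hand-built cyclic world yields its full cycle as the attractor", {
  ## deterministic 6-state cycle with one goal per lap, fed directly into the
  ## top-level graph machinery
  b <- array(0, c(6, 6, 1))
  for (i in 1:6) b[i %% 6 + 1, i, 1] <- 1
  gs <- goal_spec(c(T, F, F, F, F, F), t_max = 32L)
  expect_identical(basins(b, gs)$retained, rep(TRUE, 6))
  core <- attractor_goal_set(b, gs)
  expect_identical(core, c(TRUE, rep(FALSE, 5)))   # the goal reaches itself
})
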