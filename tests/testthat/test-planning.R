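test_that("risk and ambiguity vanish for a preferred deterministic prediction", {
  A <- list(diag(2) * 8)
  B <- array(cbind(c(1, 0), c(1, 0)), c(2, 2, 1))   # everything goes to state 1
  m <- dgm(A, B, c = list(c(1, 0)))                 # outcome 1 preferred...
  m$c <- list(c(1e6, 1e-6))                          # ...almost deterministically
  post <- list(s = matrix(c(1, 0), 2, 1))
  g <- expected_free_energy(m, post, 1L)
  expect_lt(g$risk, 1e-5)
  expect_lt(g$ambiguity, 1e-12)
})

test_that("risk against uniform preferences is log K minus predictive entropy", {
  for (sd in 1:6) {
    m <- random_dgm(S = 3L, G = 1L, U = 2L, O = 4L, seed = 400 + sd)
    m$c <- list(rep(1, 4))
    post <- list(s = matrix(normalise_columns(rgamma(3, 1)), 3, 1))
    g <- expected_free_energy(m, post, 1L)
    pred <- as.vector(normalise_columns(m$A[[1]]) %*%
                        (normalise_columns(m$B)[, , 1] %*% post$s[, 1]))
    H <- -sum(pred[pred > 0] * log(pred[pred > 0]))
    expect_equal(g$risk, log(4) - H, tolerance = 1e-10)
    expect_gte(g$risk, -1e-12)
    expect_gte(g$ambiguity, -1e-12)
    ## decomposition identity: G recomputed from its parts
    expect_equal(g$G, g$risk + g$ambiguity - g$novelty, tolerance = 1e-12)
  }
  ## novelty term is available behind the flag and non-negative here
  m <- random_dgm(S = 3L, G = 1L, U = 1L, O = 3L, seed = 1)
  m$c <- list(rep(1, 3))
  post <- list(s = matrix(rep(1 / 3, 3), 3, 1))
  gn <- expected_free_energy(m, post, 1L, include_novelty = TRUE)
  expect_gte(gn$novelty, 0)
})

test_that("parameter EFE is cross entropy minus mutual information", {
  ## uniform preferences make the cross entropy log K regardless of a
  a <- matrix(rgamma(6, 1), 2)
  expect_equal(parameter_efe(a, rep(1, 2)),
               log(2) - dirichlet_mutual_info(a), tolerance = 1e-12)
  expect_equal(parameter_efe(diag(2), rep(1, 2)), 0, tolerance = 1e-12)
  ## raising mutual information at fixed marginals lowers G
  lo <- matrix(c(1, 1, 1, 1), 2)
  hi <- matrix(c(2, 0, 0, 2), 2)   # same marginals, maximal dependence
  expect_lt(parameter_efe(hi, rep(1, 2)), parameter_efe(lo, rep(1, 2)))
  ## zero preference mass on a realised outcome is infinitely costly
  expect_identical(parameter_efe(matrix(c(1, 1), 2), c(1, 0)), Inf)
})

test_that("inductive distances equal breadth-first search on random digraphs", {
  ## hand-countable chain
  b <- array(0, c(3, 3, 1))
  b[2, 1, 1] <- 1; b[3, 2, 1] <- 1
  plan <- inductive_mask(b, goal_spec(c(FALSE, FALSE, TRUE)), horizon = 8L)
  expect_equal(plan$dist, c(2, 1, 0))
  expect_true(plan$mask[1, 2] && plan$mask[2, 1])
  ## unreachable goal signals no path from that state
  b2 <- array(0, c(3, 3, 1)); b2[2, 1, 1] <- 1
  plan2 <- inductive_mask(b2, goal_spec(c(FALSE, FALSE, TRUE)), horizon = 8L)
  expect_true(is.infinite(plan2$dist[1]))
  ## oracle equivalence over many random digraphs, with and without costs
  for (sd in 1:100) {
    n <- sample(8:20, 1)
    b3 <- random_digraph_b(n = n, p = 0.15, seed = 500 + sd)
    gamma <- rep(FALSE, n); gamma[sample(n, 2)] <- TRUE
    chi <- rep(FALSE, n)
    chi[sample(which(!gamma), 2)] <- TRUE
    gs <- goal_spec(gamma, chi, t_max = 32L)
    plan3 <- inductive_mask(b3, gs, horizon = 32L)
    expect_equal(plan3$dist, unname(oracle_goal_dist(b3, gs$gamma, which(chi), 32L)))
  }
})

test_that("path selection prefers the shortest route and breaks ties low", {
  ## two paths reaching goal in 2 vs 3 steps
  b <- array(0, c(5, 5, 2))
  b[2, 1, 1] <- 1; b[3, 2, 1] <- 1   # 1 -> 2 -> 3 (goal), path 1 from state 1
  b[4, 1, 2] <- 1; b[5, 4, 1] <- 1; b[3, 5, 1] <- 1  # 1 -> 4 -> 5 -> 3
  m <- dgm(list(matrix(1, 2, 5)), b)
  plan <- inductive_mask(b, goal_spec(c(F, F, T, F, F)), horizon = 8L)
  sel <- select_path(m, 1L, plan)
  expect_identical(sel$path, 1L)
  expect_identical(sel$successor, 2L)
  expect_false(sel$fallback)
  ## single admissible decreasing path is forced
  sel2 <- select_path(m, 4L, plan)
  expect_identical(sel2$successor, 5L)
  ## ties break to the lowest path index
  b4 <- array(0, c(4, 4, 3))
  b4[2, 1, 1] <- 1; b4[3, 1, 2] <- 1; b4[4, 2, 1] <- 1; b4[4, 3, 1] <- 1
  plan4 <- inductive_mask(b4, goal_spec(c(F, F, F, T)), horizon = 8L)
  m4 <- dgm(list(matrix(1, 2, 4)), b4)
  sel4 <- select_path(m4, 1L, plan4)
  expect_identical(sel4$path, 1L)
})

test_that("action selection realises proprioceptive predictions", {
  pred <- c(0, 0, 1, 0)          # predicted paddle at column 3
  outcomes <- c(1L, 2L, 3L)      # left/stay/right land at columns 1..3
  expect_identical(select_action(pred, outcomes, greedy = TRUE), 3L)
  set.seed(1)
  draws <- replicate(200, select_action(pred, outcomes, precision = 512))
  expect_gt(mean(draws == 3L), 0.999 - 1e-9)
  ## uniform prediction gives a uniform action distribution
  draws2 <- replicate(600, select_action(rep(0.25, 4), outcomes))
  expect_gt(min(table(factor(draws2, levels = 1:3))), 120)
  ## closed-form softmax at precision 512 saturates on the most accurate
  p <- softmax(c(0.5, 0.3, 0.2)[c(1L, 2L, 3L)], 512)
  expect_gt(p[1], 1 - 1e-9)
})
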