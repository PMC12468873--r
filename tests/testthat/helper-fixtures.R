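## Shared fixtures, built lazily once per test run.

.fx <- new.env()

## the full three-phase pipeline under the default study conditions
fixture_pipeline <- function() {
  if (is.null(.fx$pipe)) {
    cfg <- denovo_config(seed = 1L)
    frames <- play_frames(new_game(cfg$game, seed = cfg$seed), cfg$frames,
                          "random")
    m1 <- learn_structure(frames$obs, cfg)
    m2 <- learn_attractor(m1, cfg)
    m3 <- learn_continual(m2, cfg)
    .fx$pipe <- list(cfg = cfg, frames = frames, m1 = m1, m2 = m2, m3 = m3)
  }
  .fx$pipe
}

fixture_merged <- function() {
  if (is.null(.fx$merged)) .fx$merged <- merge_preserving_mi(fixture_pipeline()$m3)
  .fx$merged
}

## the goal-threshold-32 preset, with evaluation before and after continual
## learning
fixture_ablation <- function() {
  if (is.null(.fx$abl)) {
    p <- fixture_pipeline()
    cfg <- denovo_config(seed = 1L, goal_threshold = 32L)
    m2 <- learn_attractor(p$m1, cfg)
    pre <- play_model(m2, cfg, games = 10L)
    m3 <- learn_continual(m2, cfg)
    .fx$abl <- list(cfg = cfg, m2 = m2, pre = pre, m3 = m3)
  }
  .fx$abl
}

## the engine's analytic per-200-frame reward ceiling, realised by an oracle
## player (the parked paddle returns every ball vertically through the
## central columns; all volleys share the same vertical period, so no policy
## reaches a reward sooner)
fixture_ceiling <- function(cfg = denovo_config()) {
  r <- play_frames(new_game(cfg$game), cfg$game_frames, "stay")
  stopifnot(sum(r$lost) == 0L)
  sum(r$rewarded)
}

## small random dense models for oracle comparisons
random_dgm <- function(S = 3L, G = 2L, U = 2L, O = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- replicate(G, matrix(stats::rgamma(O * S, 1), O, S), simplify = FALSE)
  B <- array(stats::rgamma(S * S * U, 1), c(S, S, U))
  dgm(A, B, d = stats::rgamma(S, 1), e = stats::rgamma(U, 1),
      c = replicate(G, stats::rgamma(O, 1), simplify = FALSE))
}

## exact posterior marginals and log evidence by exhaustive enumeration over
## all state trajectories and paths
enumerate_posterior <- function(model, obs_seq) {
  S <- model$S; U <- model$U; Tn <- length(obs_seq)
  Ab <- lapply(model$A, normalise_columns)
  Bb <- normalise_columns(model$B)
  db <- normalise_columns(model$d)
  eb <- normalise_columns(model$e)
  lik <- function(obs, s) {
    p <- 1
    for (g in seq_along(Ab)) {
      o <- obs[[g]]
      oi <- if (length(o) == 1L) o else which.max(o)
      p <- p * Ab[[g]][oi, s]
    }
    p
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  smarg <- matrix(0, S, Tn)
  umarg <- numeric(U)
  Z <- 0
  for (u in seq_len(U)) for (r in seq_len(nrow(paths))) {
    traj <- paths[r, ]
    p <- eb[u] * db[traj[1L]] * lik(obs_seq[[1L]], traj[1L])
    if (Tn > 1L) for (t in 2L:Tn)
      p <- p * Bb[traj[t], traj[t - 1L], u] * lik(obs_seq[[t]], traj[t])
    Z <- Z + p
    umarg[u] <- umarg[u] + p
    for (t in seq_len(Tn)) smarg[traj[t], t] <- smarg[traj[t], t] + p
  }
  list(s = smarg / Z, u = umarg / Z, logZ = log(Z))
}

## random sparse digraph as a count tensor, for graph-oracle comparisons
random_digraph_b <- function(n = 20L, p = 0.12, max_paths = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  b <- array(0, c(n, n, max_paths))
  e <- which(adj, arr.ind = TRUE)
  if (nrow(e)) {
    slot <- unlist(lapply(split(seq_len(nrow(e)), e[, 2L]), seq_along))
    ord <- order(e[, 2L])
    b[cbind(e[ord, 1L], e[ord, 2L], pmin(slot, max_paths))] <- 1
  }
  b
}

## igraph-based distance oracle on the same edge set (distances to the
## nearest goal through non-costly states)
oracle_goal_dist <- function(b, gamma, chi, horizon) {
  adjm <- apply(b, c(1, 2), sum) > 0
  adjm[chi, ] <- FALSE
  adjm[, chi] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(t(adjm * 1), mode = "directed")
  d <- igraph::distances(g, to = which(gamma), mode = "out")
  out <- apply(d, 1L, min)
  out[out > horizon] <- Inf
  out[chi] <- Inf
  out
}
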