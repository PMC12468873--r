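#' Mark goal and costly generalised states
#'
#' A goal state is a top-level state whose predicted observations over the
#' frames it covers include the reward symbol; a costly state predicts a
#' punishment.  Costliness takes precedence where both hold.
#'
#' @param model a \code{denovo_model} with a trained top level.
#' @return a \code{\link{goal_spec}} over the top-level states.
#' @export
mark_goal_cost_states <- function(model) {
  streams <- vapply(model$factors, function(f) f$stream, "")
  if (!any(streams == "reward")) stop("missing reward stream")
  top <- model$top
  n <- top$n_states
  if (!is.null(top$members)) {    # merged model: flags already aggregated
    return(goal_spec(top$goal & top$active, top$cost & top$active,
                     t_max = model$config$basin_horizon))
  }
  .mark_goal_cost(model, seq_len(n))
  goal_spec(top$goal & top$active, top$cost & top$active,
            t_max = model$config$basin_horizon)
}

#' Basins of attraction of goal states
#'
#' Propagates the goal set backwards and forwards through the logical
#' transition matrix over non-costly states (collapsing the path dimension),
#' up to \code{goals$t_max} transitions, and retains the states in either
#' orbit or in the goal set itself.
#'
#' @param b_top transition count tensor (\code{[to, from, path]}) or logical
#'   adjacency matrix.
#' @param goals a \code{\link{goal_spec}}.
#' @return list with \code{retained} (logical) and \code{R}, the 0/1
#'   column-selection matrix of the retained states.
#' @export
basins <- function(b_top, goals) {
  stopifnot(any(goals$gamma))
  adj <- .adj_from_b(b_top, chi = which(goals$chi))
  g <- which(goals$gamma)
  back <- .bfs_dist(adj$into, g, goals$t_max)   # ancestors: reach a goal
  fwd <- .bfs_dist(adj$out, g, goals$t_max)     # descendants: reached from a goal
  retained <- (!goals$chi) & (goals$gamma | is.finite(back) | is.finite(fwd))
  if (!any(retained)) stop("empty retained set")
  R <- diag(length(retained))[, retained, drop = FALSE]
  list(retained = retained, R = R)
}

#' Slice top-level tensors to a retained state subset
#'
#' @param b transition count tensor (\code{[to, from, path]}).
#' @param a list of likelihood count matrices with states on the column axis.
#' @param retained logical vector of states to keep.
#' @return list with the sliced \code{b} (empty path slots dropped) and
#'   \code{a}.
#' @export
reduce_tensors <- function(b, a, retained) {
  stopifnot(any(retained))
  b2 <- b[retained, retained, , drop = FALSE]
  live <- apply(b2, 3L, sum) > 0
  if (any(live)) b2 <- b2[, , live, drop = FALSE]
  list(b = b2, a = lapply(a, function(m) m[, retained, drop = FALSE]))
}

#' Reduce a model to a retained subset of generalised states
#'
#' Removes the complement of \code{retained} from the top level: their
#' counts and priors are dropped, transitions touching them are deleted, and
#' path slots are renumbered per source state (empty slots disappear).
#' Lower-level tensors are untouched.
#'
#' @param model a \code{denovo_model}.
#' @param retained logical vector over top-level states.
#' @return a new, reduced \code{denovo_model}.
#' @export
reduce_model <- function(model, retained) {
  stopifnot(length(retained) == model$top$n_states, any(retained))
  m <- .model_clone(model)
  .deactivate(m, retained)
  m
}

#' Mutually reachable goal core (the pullback attractor's goal set)
#'
#' Returns the goal states that are pairwise mutually reachable within
#' \code{goals$t_max} steps through non-costly states: the strongly
#' connected core of the goal reachability graph (goals reaching themselves
#' within the horizon count as their own core).
#'
#' @param b_top transition count tensor or logical adjacency matrix.
#' @param goals a \code{\link{goal_spec}}.
#' @return logical vector over states marking the goal core.
#' @export
attractor_goal_set <- function(b_top, goals) {
  adj <- .adj_from_b(b_top, chi = which(goals$chi))
  .goal_core_adj(adj$out, which(goals$gamma), goals$t_max,
                 length(goals$gamma))
}

.goal_core_adj <- function(adj_out, gidx, t_max, n) {
  core <- logical(n)
  if (!length(gidx)) return(core)
  edges <- vector("list", length(gidx))
  selfs <- logical(length(gidx))
  for (k in seq_along(gidx)) {
    g <- gidx[k]
    d <- .bfs_dist(adj_out, g, t_max)
    hit <- gidx[is.finite(d[gidx])]
    edges[[k]] <- hit[hit != g]
    ## g lies on a closed orbit of length <= t_max through itself
    within <- which(d <= t_max - 1)
    selfs[k] <- length(within) &&
      any(unlist(adj_out[within], use.names = FALSE) == g)
  }
  core[gidx[selfs]] <- TRUE
  ne <- lengths(edges)
  if (sum(ne)) {
    gmap <- match(unlist(edges, use.names = FALSE), gidx)
    gfrom <- rep(seq_along(gidx), ne)
    gr <- igraph::make_empty_graph(n = length(gidx), directed = TRUE)
    gr <- igraph::add_edges(gr, rbind(gfrom, gmap))
    comp <- igraph::components(gr, mode = "strong")
    big <- which(tabulate(comp$membership, comp$no) >= 2L)
    core[gidx[comp$membership %in% big]] <- TRUE
  }
  core
}

#' Recursively remove states with no successors
#'
#' Repeatedly deletes states whose transition columns are empty until a
#' fixed point; orphan states (no predecessors) are retained as initial
#' conditions.
#'
#' @param x a square logical/count adjacency matrix (\code{[to, from]}) or a
#'   \code{denovo_model}.
#' @param ... unused.
#' @return for a matrix: list with \code{retained} and the reduced
#'   \code{adjacency}; for a model: the pruned model.
#' @export
prune_dead_ends <- function(x, ...) UseMethod("prune_dead_ends")

#' @export
prune_dead_ends.default <- function(x, ...) {
  m <- x > 0
  retained <- rep(TRUE, nrow(m))
  repeat {
    sinks <- retained & colSums(m[retained, , drop = FALSE] > 0) == 0
    sinks[!retained] <- FALSE
    if (!any(sinks)) break
    retained[sinks] <- FALSE
    m[, sinks] <- FALSE
    m[sinks, ] <- FALSE
  }
  if (!any(retained)) stop("everything pruned: no recurrent states")
  list(retained = retained, adjacency = m)
}

#' @export
prune_dead_ends.denovo_model <- function(x, ...) {
  m <- .model_clone(x)
  top <- m$top
  repeat {
    od <- .active_outdeg(m)
    dead <- top$active & od == 0L
    if (!any(dead)) break
    top$active[dead] <- FALSE
  }
  if (!any(top$active)) stop("everything pruned: no recurrent states")
  .drop_dead_transitions(m)
  m
}

#' Transitive reduction of a directed graph
#'
#' Returns a directed graph with the same vertices and the same transitive
#' closure but a minimal edge set.  Cyclic graphs are reduced on their
#' condensation: the strongly connected components are contracted, the
#' acyclic quotient is reduced, and each non-trivial component is replaced
#' by a single cycle through its members.
#'
#' @param adjacency square logical matrix (\code{[to, from]} or symmetric
#'   interpretation \code{[i, j]}: edge j -> i).
#' @return logical adjacency matrix of the reduction.
#' @export
transitive_reduction <- function(adjacency) {
  a <- adjacency > 0
  n <- nrow(a)
  stopifnot(ncol(a) == n)
  gr <- igraph::graph_from_adjacency_matrix(t(a * 1), mode = "directed")
  comp <- igraph::components(gr, mode = "strong")
  k <- comp$no
  memb <- comp$membership
  ## condensation edges (j -> i in column convention)
  cond <- matrix(FALSE, k, k)
  e <- which(a, arr.ind = TRUE)
  if (nrow(e)) {
    ci <- memb[e[, 1L]]
    cj <- memb[e[, 2L]]
    keep <- ci != cj
    cond[cbind(ci[keep], cj[keep])] <- TRUE
  }
  ## transitive reduction of the DAG: drop edges implied by longer paths
  closure <- cond
  repeat {
    nxt <- (closure %*% closure + closure) > 0
    if (identical(nxt, closure)) break
    closure <- nxt
  }
  red_cond <- cond & !((closure %*% closure) > 0)
  out <- matrix(FALSE, n, n)
  reps <- vapply(seq_len(k), function(cc) which(memb == cc)[1L], 1L)
  ee <- which(red_cond, arr.ind = TRUE)
  if (nrow(ee)) out[cbind(reps[ee[, 1L]], reps[ee[, 2L]])] <- TRUE
  for (cc in seq_len(k)) {
    mem <- which(memb == cc)
    if (length(mem) > 1L)
      out[cbind(c(mem[-1L], mem[1L]), mem)] <- TRUE
  }
  out
}

## ---- internal graph utilities over the compact top level -----------------

.live_tids <- function(top) {
  which(top$tr$count > 0 &
          top$active[pmax(top$tr$from, 1L)] &
          top$active[pmax(top$tr$to, 1L)] &
          top$tr$from > 0L)
}

.top_adj <- function(model, exclude_cost = TRUE) {
  top <- model$top
  n <- top$n_states
  idx <- .live_tids(top)
  from <- top$tr$from[idx]
  to <- top$tr$to[idx]
  if (exclude_cost) {
    keep <- !top$cost[to] & !top$cost[from]
    from <- from[keep]; to <- to[keep]
  }
  out <- vector("list", n)
  into <- vector("list", n)
  if (length(from)) {
    sp <- split(to, from)
    out[as.integer(names(sp))] <- sp
    sp2 <- split(from, to)
    into[as.integer(names(sp2))] <- sp2
  }
  out[vapply(out, is.null, NA)] <- list(integer(0))
  into[vapply(into, is.null, NA)] <- list(integer(0))
  list(out = out, into = into)
}

.active_outdeg <- function(model) {
  top <- model$top
  idx <- .live_tids(top)
  tabulate(top$tr$from[idx], top$n_states)
}

.basin_retained <- function(model, t_max) {
  top <- model$top
  gamma <- top$goal & top$active
  if (!any(gamma)) return(top$active & !top$cost)
  adj <- .top_adj(model, exclude_cost = TRUE)
  g <- which(gamma)
  back <- .bfs_dist(adj$into, g, t_max)
  fwd <- .bfs_dist(adj$out, g, t_max)
  top$active & !top$cost & (gamma | is.finite(back) | is.finite(fwd))
}

## deactivate states and physically remove transitions that touch inactive
## or costly states, re-numbering path slots per source state
.drop_dead_transitions <- function(model) {
  top <- model$top
  tr <- top$tr
  keep <- .live_tids(top)
  from <- tr$from[keep]; to <- tr$to[keep]; cnt <- tr$count[keep]
  ord <- order(from, tr$slot[keep])
  from <- from[ord]; to <- to[ord]; cnt <- cnt[ord]
  slot <- stats::ave(seq_along(from), from, FUN = seq_along)
  tr$from <- from; tr$to <- to; tr$count <- cnt
  tr$slot <- as.integer(slot)
  tr$keys <- paste(from, to)
  top$outdeg <- tabulate(from, top$n_states)
  top$counts[!top$active] <- 0
  top$d[!top$active] <- 0
  nsl <- if (length(slot)) max(slot) else 0L
  top$e <- as.numeric(tapply(cnt, factor(tr$slot, levels = seq_len(nsl)), sum))
  top$e[is.na(top$e)] <- 0
  invisible(model)
}

.deactivate <- function(model, retained) {
  top <- model$top
  if (all(retained[top$active])) return(invisible(model))
  top$active <- top$active & retained
  .drop_dead_transitions(model)
  invisible(model)
}

.goal_core_model <- function(model, t_max) {
  top <- model$top
  adj <- .top_adj(model, exclude_cost = TRUE)
  .goal_core_adj(adj$out, which(top$goal & top$active), t_max, top$n_states)
}

#' Reward-gated attractor learning (phase 2)
#'
#' Plays the bundled game under random actions in fixed-length epochs.
#' Epochs containing no reward are discarded (the hard active-learning gate);
#' rewarded epochs are assimilated bottom-up, growing states, paths and
#' Dirichlet counts, after which the model is reduced to the basins of
#' attraction of its goal states.  Learning stops when the mutually
#' reachable goal core reaches \code{config$goal_threshold} (or the epoch
#' budget is exhausted), and absorbing states are pruned.
#'
#' @param model a \code{denovo_model} from \code{\link{learn_structure}} (its
#'   counts are emptied first) or a skeleton from \code{\link{empty_counts}}.
#' @param config a \code{\link{denovo_config}}; defaults to the model's.
#' @param progress print progress every assimilated epoch check.
#' @return a new \code{denovo_model} (phase \code{"attractor"}) with an
#'   \code{attractor_converged} flag and a per-epoch history data frame in
#'   \code{$history$attractor}.
#' @export
learn_attractor <- function(model, config = model$config, progress = FALSE) {
  m <- if (model$phase %in% c("structure")) empty_counts(model) else
    .model_clone(model)
  m$config <- config
  st <- new_game(config$game, seed = config$seed)
  hist <- list()
  n_assim <- 0L
  core_n <- 0L
  converged <- FALSE
  for (i in seq_len(config$epoch_budget)) {
    r <- play_frames(st, config$epoch_frames, "random")
    st <- r$state
    if (!any(r$rewarded)) next
    .assimilate_window(m, r$obs)
    .deactivate(m, .basin_retained(m, config$basin_horizon))
    n_assim <- n_assim + 1L
    if (n_assim %% config$check_every == 0L) {
      core_n <- sum(.goal_core_model(m, config$basin_horizon))
      if (progress)
        message(sprintf("epoch %d (assimilated %d): states %d paths %d goals %d core %d",
                        i, n_assim, sum(m$top$active), n_paths(m),
                        sum(m$top$goal & m$top$active), core_n))
    }
    od <- .active_outdeg(m)
    act <- m$top$active
    hist[[length(hist) + 1L]] <-
      c(epoch = i, assimilated = n_assim, states = sum(act),
        paths = n_paths(m), goals = sum(m$top$goal & act),
        absorbing = sum(act & od == 0L),
        orphans = NA_integer_, core = core_n)
    if (core_n >= config$goal_threshold) { converged <- TRUE; break }
  }
  hist <- as.data.frame(do.call(rbind, hist))
  if (nrow(hist)) {
    adj <- .top_adj(m, exclude_cost = TRUE)
    indeg <- lengths(adj$into)
    hist$orphans[nrow(hist)] <- sum(m$top$active & indeg == 0L)
  }
  m2 <- tryCatch(prune_dead_ends(m), error = function(e) m)
  m2$phase <- "attractor"
  m2$attractor_converged <- converged
  m2$history$attractor <- hist
  m2
}

## ---- inductive play ------------------------------------------------------

.state_pattern <- function(model, id, key = NULL) {
  top <- model$top
  if (is.null(key))
    key <- if (!is.null(top$rep_keys)) top$rep_keys[id] else top$keys[id]
  .key_decode(key)[[1L]]
}

## For a merged model, resolve the planned successor to the member pattern
## that is an actual recorded successor of the current (unmerged) state:
## the pixel-level likelihoods are not merged, so observations disambiguate
## which member of an OR-state will realise.
.pred_key <- function(model, pred, cur_orig) {
  top <- model$top
  if (is.null(top$id_map)) return(top$keys[pred])
  if (!is.na(cur_orig) && !is.null(top$orig_succ) &&
      cur_orig <= length(top$orig_succ)) {
    cand <- top$orig_succ[[cur_orig]]
    mb <- intersect(top$members[[pred]], cand)
    if (length(mb)) return(top$keys[mb[1L]])
  }
  top$rep_keys[pred]
}

## identify the generalised state of a 2-frame window without touching the
## model (unknown patterns yield NA)
.identify_epoch <- function(model, obs) {
  parts <- character(2L * length(model$factors))
  for (fi in seq_along(model$factors)) {
    f <- model$factors[[fi]]
    keys <- .factor_frame_keys(obs, f$channels)
    ids <- match(keys, f$keys)
    if (anyNA(ids)) return(NA_integer_)
    tid <- match(paste(ids[1L], ids[2L]), f$tr$keys)
    if (is.na(tid)) return(NA_integer_)
    parts[2L * fi - 1L] <- ids[1L]
    parts[2L * fi] <- f$tr$slot[tid]
  }
  id <- match(paste(parts, collapse = ","), model$top$keys)
  if (is.na(id)) return(NA_integer_)
  orig <- id
  if (!is.null(model$top$id_map)) {
    if (id > length(model$top$id_map)) return(NA_integer_)
    id <- model$top$id_map[id]
  }
  attr(id, "orig") <- orig
  id
}

.plan_dist <- function(model, horizon) {
  top <- model$top
  gamma <- which(top$goal & top$active)
  if (!length(gamma)) return(rep(Inf, top$n_states))
  adj <- .top_adj(model, exclude_cost = TRUE)
  .bfs_dist(adj$into, gamma, horizon)
}

## successors (to, slot) per state, from the live transition triplets
.succ_index <- function(model) {
  top <- model$top
  idx <- .live_tids(top)
  ord <- idx[order(top$tr$from[idx], top$tr$slot[idx])]
  sp_to <- split(top$tr$to[ord], top$tr$from[ord])
  sp_ct <- split(top$tr$count[ord], top$tr$from[ord])
  succ <- vector("list", top$n_states)
  cts <- vector("list", top$n_states)
  succ[as.integer(names(sp_to))] <- sp_to
  cts[as.integer(names(sp_ct))] <- sp_ct
  list(succ = succ, counts = cts)
}

.pref_logs <- function() {
  ## preferences fixed by stream semantics: reward outcome preferred,
  ## punishment outcome costly (64:1 odds each way)
  list(reward = log(c(1, 64) / 65), punishment = log(c(64, 1) / 65))
}

## risk of committing to a successor state, from its predicted reward and
## punishment symbols over the covered frames
.succ_risk <- function(model, id, pref) {
  pat <- .state_pattern(model, id)
  streams <- vapply(model$factors, function(f) f$stream, "")
  risk <- 0
  for (nm in c("reward", "punishment")) {
    fi <- which(streams == nm)
    if (!length(fi)) next
    f <- model$factors[[fi]]
    s0 <- pat[2L * fi - 1L]
    u <- pat[2L * fi]
    syms <- as.integer(f$keys[s0])
    nxt <- f$tr$to[f$tr$from == s0 & f$tr$slot == u]
    if (length(nxt)) syms <- c(syms, as.integer(f$keys[nxt[1L]]))
    risk <- risk - sum(pref[[nm]][syms])
  }
  risk
}

## paddle columns predicted by a successor state over its two frames
.succ_paddle <- function(model, id, key = NULL) {
  pat <- .state_pattern(model, id, key)
  streams <- vapply(model$factors, function(f) f$stream, "")
  fi <- which(streams == "proprio")
  if (!length(fi)) return(c(NA_integer_, NA_integer_))
  f <- model$factors[[fi]]
  s0 <- pat[2L * fi - 1L]
  u <- pat[2L * fi]
  c1 <- as.integer(f$keys[s0])
  nxt <- f$tr$to[f$tr$from == s0 & f$tr$slot == u]
  c2 <- if (length(nxt)) as.integer(f$keys[nxt[1L]]) else c1
  c(c1, c2)
}

.realise_action <- function(paddle, target, precision, n_cols, greedy = FALSE) {
  if (is.na(target)) return(2L)
  res <- pmin(pmax(paddle + (-1:1), 1L), n_cols)
  acc <- as.numeric(res == target)
  if (!any(acc > 0)) return(if (target > paddle) 3L else 1L)
  if (greedy) which.max(softmax(acc, precision)) else
    sample.int(3L, 1L, prob = softmax(acc, precision))
}

## one game of inductive play; mutates the model when learn = TRUE
.play_game <- function(model, st, frames, learn = TRUE, greedy = FALSE) {
  cfgr <- model$config
  jit <- cfgr$jitter
  pref <- .pref_logs()
  dist <- .plan_dist(model, cfgr$induction_horizon)
  sx <- .succ_index(model)
  top <- model$top
  nE <- frames %/% 2L
  elbo_f <- numeric(2L * nE)
  rewards <- 0L; losses <- 0L; fallbacks <- 0L
  cur <- NA_integer_
  cur_orig <- NA_integer_
  for (k in seq_len(nE)) {
    pred <- NA_integer_
    cand <- if (is.na(cur)) integer(0) else if (!is.null(top$id_map)) {
      ## merged model: only successors realisable from the current member
      co <- if (!is.na(cur_orig) && !is.null(top$orig_succ) &&
                cur_orig <= length(top$orig_succ))
        top$orig_succ[[cur_orig]] else integer(0)
      if (length(co)) unique(top$id_map[co][!is.na(top$id_map[co])]) else
        if (cur <= length(sx$succ) && !is.null(sx$succ[[cur]]))
          sx$succ[[cur]] else integer(0)
    } else if (cur <= length(sx$succ) && !is.null(sx$succ[[cur]]))
      sx$succ[[cur]] else integer(0)
    if (length(cand)) {
      dd <- ifelse(cand <= length(dist), dist[pmin(cand, length(dist))], Inf)
      dcur <- if (cur <= length(dist)) dist[cur] else Inf
      ## at a goal (distance 0) the next target is the nearest other goal,
      ## so the strict-decrease requirement restarts
      ok <- if (is.finite(dcur) && dcur == 0) which(is.finite(dd)) else
        which(is.finite(dd) & dd < dcur)
      if (length(ok)) {
        pred <- cand[ok[which.min(dd[ok])]]
      } else {
        fallbacks <- fallbacks + 1L
        g <- vapply(cand, function(s2) .succ_risk(model, s2, pref), 0)
        pred <- cand[sample.int(length(cand), 1L, prob = softmax(-g))]
      }
    } else if (!is.na(cur)) fallbacks <- fallbacks + 1L
    pc <- if (!is.na(pred))
      .succ_paddle(model, pred, key = .pred_key(model, pred, cur_orig)) else
      c(NA_integer_, NA_integer_)
    a1 <- .realise_action(st$paddle_col, pc[1L], cfgr$action_precision,
                          cfgr$game$n_cols, greedy)
    s1 <- game_step(st, a1)
    a2 <- .realise_action(s1$state$paddle_col, pc[2L], cfgr$action_precision,
                          cfgr$game$n_cols, greedy)
    s2 <- game_step(s1$state, a2)
    st <- s2$state
    obs2 <- cbind(s1$obs, s2$obs)
    rewards <- rewards + s1$rewarded + s2$rewarded
    losses <- losses + s1$lost + s2$lost
    actual <- if (learn) .assimilate_window(model, obs2, count = TRUE,
                                            prev_top = cur)
              else .identify_epoch(model, obs2)
    ## evidence-bound accounting: transition surprise at the top level plus
    ## cause-level prediction mismatches
    lp <- log(jit) - log(1)
    if (!is.na(cur) && !is.na(actual)) {
      ct <- if (cur <= length(sx$succ)) sx$counts[[cur]] else numeric(0)
      cd <- if (cur <= length(sx$succ)) sx$succ[[cur]] else integer(0)
      tot <- sum(ct) + jit * max(1L, sum(top$active))
      hit <- ct[cd == actual]
      lp <- log((if (length(hit)) hit[1L] else 0) + jit) - log(tot)
    }
    mism <- if (!is.na(pred) && !is.na(actual) && pred != actual) {
      sum(.state_pattern(model, pred) != .state_pattern(model, actual))
    } else if (is.na(pred) || is.na(actual)) 2L else 0L
    ev <- lp + mism * log(1 / 512)
    elbo_f[2L * k - 1L] <- ev / 2
    elbo_f[2L * k] <- ev / 2
    cur_orig <- if (!is.null(attr(actual, "orig"))) attr(actual, "orig") else
      actual
    cur <- as.integer(actual)
  }
  list(state = st, rewards = as.integer(rewards), losses = as.integer(losses),
       elbo = elbo_f, fallbacks = fallbacks)
}

#' Continual learning by inductive active inference (phase 3)
#'
#' Turns the reduced model into an agent: each frame pair, the agent infers
#' its generalised state, selects the transition whose successor strictly
#' decreases the backward-induction distance to the nearest goal (falling
#' back on an expected-free-energy path prior when no such transition
#' exists), and realises the successor's proprioceptive predictions through
#' high-precision action selection.  Novel states and transitions landing in
#' the basins of attraction are assimilated after each game, followed by
#' model reduction.  Transition tensors carry a small concentration
#' parameter (\code{config$jitter}) so that prior precision does not override
#' sensory evidence.
#'
#' @param model a phase-2 \code{denovo_model}.
#' @param config a \code{\link{denovo_config}}.
#' @param progress print per-game performance.
#' @return a new \code{denovo_model} (phase \code{"continual"}) with a
#'   per-game performance log in \code{$history$continual} and per-frame
#'   evidence-bound traces in \code{$history$elbo}.
#' @export
learn_continual <- function(model, config = model$config, progress = FALSE) {
  m <- .model_clone(model)
  m$config <- config
  set.seed(config$seed + 7L)
  logs <- list()
  elbos <- list()
  for (g in seq_len(config$games)) {
    st <- new_game(config$game, seed = (config$seed + 104729 * g) %% 2147483647)
    res <- .play_game(m, st, config$game_frames, learn = TRUE)
    .deactivate(m, .basin_retained(m, config$basin_horizon))
    logs[[g]] <- c(game = g, rewards = res$rewards, losses = res$losses,
                   states = sum(m$top$active), paths = n_paths(m),
                   elbo = sum(res$elbo), fallbacks = res$fallbacks)
    elbos[[g]] <- res$elbo
    if (progress)
      message(sprintf("game %d: %d rewards, %d losses, ELBO %.1f, states %d",
                      g, res$rewards, res$losses, sum(res$elbo),
                      sum(m$top$active)))
  }
  m$phase <- "continual"
  m$history$continual <- as.data.frame(do.call(rbind, logs))
  m$history$elbo <- elbos
  m
}

#' Evaluate a model by playing without learning
#'
#' @param model a trained \code{denovo_model}.
#' @param config a \code{\link{denovo_config}}.
#' @param games,game_frames schedule (default from \code{config}).
#' @param seed seed offset for the evaluation games.
#' @return data frame with per-game rewards, losses, summed evidence bound
#'   and fallback counts, with per-frame traces in \code{attr(,"elbo")}.
#' @export
play_model <- function(model, config = model$config, games = config$games,
                       game_frames = config$game_frames, seed = config$seed) {
  m <- .model_clone(model)   # dictionaries may grow during identification
  set.seed(seed + 13L)
  logs <- list()
  elbos <- list()
  for (g in seq_len(games)) {
    st <- new_game(config$game, seed = (seed + 15485863 * g) %% 2147483647)
    res <- .play_game(m, st, game_frames, learn = FALSE)
    logs[[g]] <- c(game = g, rewards = res$rewards, losses = res$losses,
                   elbo = sum(res$elbo), fallbacks = res$fallbacks)
    elbos[[g]] <- res$elbo
  }
  out <- as.data.frame(do.call(rbind, logs))
  attr(out, "elbo") <- elbos
  out
}

#' Merge generalised states that preserve trailing-stream predictions
#'
#' Builds, for each top-level state, the stacked likelihood columns of its
#' trailing-stream (reward, punishment, proprioceptive) cause mappings and
#' their one-step propagation through the top transition tensor, discounting
#' the pixel stream, and merges states whose stacked columns fall within one
#' natural unit of information distance.  The merged states predict one
#' combination of outcomes OR another, preserving the mutual information
#' that inductive inference needs.
#'
#' @param model a trained \code{denovo_model} (phase 3).
#' @return a new \code{denovo_model} (phase \code{"merged"}) whose top level
#'   is expressed over merged states; observation patterns map onto merged
#'   states during play.
#' @export
merge_preserving_mi <- function(model) {
  m <- .model_clone(model)
  top <- m$top
  act <- which(top$active)
  nA <- length(act)
  if (nA < 2L) return(m)
  streams <- vapply(m$factors, function(f) f$stream, "")
  trailing <- which(streams != "pixel")
  if (!length(trailing)) stop("need at least one non-pixel stream")
  pats <- .key_decode(top$keys[act])
  idx <- .live_tids(top)
  keepa <- top$active[top$tr$from[idx]] & top$active[top$tr$to[idx]]
  fr <- match(top$tr$from[idx][keepa], act)
  to <- match(top$tr$to[idx][keepa], act)
  ct <- top$tr$count[idx][keepa]
  Bn <- Matrix::sparseMatrix(i = to, j = fr, x = ct, dims = c(nA, nA))
  cs <- Matrix::colSums(Bn)
  cs[cs == 0] <- 1
  Bn <- Bn %*% Matrix::Diagonal(x = 1 / cs)
  blocks <- list()
  for (fi in trailing) {
    f <- m$factors[[fi]]
    K <- .tab_n(f)
    P <- max(1L, if (length(f$tr$slot)) max(f$tr$slot) else 1L)
    s0 <- vapply(pats, function(p) p[2L * fi - 1L], 1L)
    u <- vapply(pats, function(p) p[2L * fi], 1L)
    D <- matrix(0, K, nA); D[cbind(s0, seq_len(nA))] <- 1
    E <- matrix(0, P, nA); E[cbind(pmin(u, P), seq_len(nA))] <- 1
    blocks[[length(blocks) + 1L]] <- D
    blocks[[length(blocks) + 1L]] <- E
    blocks[[length(blocks) + 1L]] <- as.matrix(D %*% Bn)
    blocks[[length(blocks) + 1L]] <- as.matrix(E %*% Bn)
  }
  O <- do.call(rbind, blocks)
  uc <- unique_columns(O, precise = FALSE, G = length(blocks))
  grp <- match(uc$k, uc$groups)       # merged index per active state
  K2 <- max(grp)
  id_map <- rep(NA_integer_, top$n_states)
  id_map[act] <- grp
  members <- split(act, grp)
  agg <- function(v) as.numeric(tapply(v[act], grp, sum))
  counts2 <- agg(top$counts)
  d2 <- agg(top$d)
  goal2 <- vapply(members, function(mm) any(top$goal[mm]), NA)
  cost2 <- vapply(members, function(mm) any(top$cost[mm]), NA)
  goal2 <- goal2 & !cost2
  rep_keys <- vapply(members, function(mm) top$keys[mm[which.max(top$counts[mm])]], "")
  ## merged transitions: aggregate by merged endpoints, re-slot per source
  mf <- grp[fr]; mt <- grp[to]
  kk <- paste(mf, mt)
  uk <- unique(kk)
  tid <- match(kk, uk)
  c2 <- as.numeric(tapply(ct, tid, sum))
  ufrom <- mf[match(uk, kk)]
  uto <- mt[match(uk, kk)]
  ord <- order(ufrom)
  ufrom <- ufrom[ord]; uto <- uto[ord]; c2 <- c2[ord]
  slot <- as.integer(stats::ave(seq_along(ufrom), ufrom, FUN = seq_along))
  top$n_states <- K2
  top$counts <- counts2
  top$d <- d2
  top$e <- as.numeric(tapply(c2, factor(slot, levels = seq_len(max(slot))), sum))
  top$e[is.na(top$e)] <- 0
  top$goal <- goal2
  top$cost <- cost2
  top$active <- rep(TRUE, K2)
  top$outdeg <- tabulate(ufrom, K2)
  top$id_map <- id_map
  top$members <- members
  top$rep_keys <- rep_keys
  ## unmerged successor index: observations disambiguate OR-state members
  osucc <- vector("list", max(act))
  sp <- split(act[to], act[fr])
  osucc[as.integer(names(sp))] <- sp
  top$orig_succ <- osucc
  top$tr$from <- ufrom; top$tr$to <- uto; top$tr$slot <- slot
  top$tr$count <- c2
  top$tr$keys <- paste(ufrom, uto)
  m$phase <- "merged"
  m
}
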