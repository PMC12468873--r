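#' Expected free energy of a path
#'
#' Decomposes the expected free energy of following a path for one step into
#' risk (KL from predicted outcomes to the preference distribution),
#' ambiguity (expected conditional entropy of the likelihood) and, behind a
#' flag, novelty (expected Dirichlet information gain of the likelihood
#' counts).
#'
#' @param model a \code{\link{dgm}} with preference counts \code{c}.
#' @param posterior a \code{"denovo_posterior"} (or list with \code{s}).
#' @param path path index.
#' @param include_novelty logical; subtract the expected information gain.
#' @return list with \code{G}, \code{risk}, \code{ambiguity}, \code{novelty}.
#' @export
expected_free_energy <- function(model, posterior, path,
                                 include_novelty = FALSE) {
  if (is.null(model$c)) stop("undefined preferences: model has no c counts")
  s <- posterior$s[, ncol(posterior$s)]
  Bb <- normalise_columns(model$B)
  q <- as.vector(Bb[, , path] %*% s)
  risk <- 0
  ambiguity <- 0
  novelty <- 0
  for (g in seq_len(model$G)) {
    if (sum(model$c[[g]]) <= 0) stop("undefined preferences: zero c counts")
    Ab <- normalise_columns(model$A[[g]])
    pred <- as.vector(Ab %*% q)
    pref <- normalise_columns(model$c[[g]])
    nz <- pred > 0
    risk <- risk + sum(pred[nz] * (log(pred[nz]) - .log_floor(pref)[nz]))
    Hcond <- -colSums(Ab * .log_floor(Ab) * (Ab > 0))
    ambiguity <- ambiguity + sum(q * Hcond)
    if (include_novelty) {
      a <- pmax(model$A[[g]], 1e-16)
      a0 <- rep(colSums(a), each = nrow(a))
      W <- 0.5 * (1 / a - 1 / a0)
      novelty <- novelty + sum((Ab * rep(q, each = nrow(a))) * W)
    }
  }
  list(G = risk + ambiguity - novelty, risk = risk, ambiguity = ambiguity,
       novelty = novelty)
}

#' Expected free energy of Dirichlet likelihood counts
#'
#' Scores a count matrix as expected cost minus the mutual information it
#' encodes: \code{G(a) = C(a) - I(a)}, with \code{C(a)} the cross entropy of
#' the outcome marginal of the normalised counts under the normalised
#' preferences.
#'
#' @param a non-negative count matrix (outcomes x states) with positive
#'   total.
#' @param c preference counts over outcomes.
#' @param use_digamma passed to \code{\link{dirichlet_mutual_info}}.
#' @return nats; \code{+Inf} if an outcome with positive marginal carries
#'   zero preference mass.
#' @export
parameter_efe <- function(a, c, use_digamma = FALSE) {
  if (sum(a) <= 0) stop("all-zero counts")
  m <- rowSums(a / sum(a))
  cb <- normalise_columns(c)
  if (any(m > 0 & cb == 0)) return(Inf)
  nz <- m > 0
  C <- -sum(m[nz] * log(cb[nz]))
  C - dirichlet_mutual_info(a, use_digamma = use_digamma)
}

#' Goal specification over top-level states
#'
#' @param gamma logical vector marking goal states.
#' @param chi logical vector marking costly states; costliness takes
#'   precedence where the two overlap.
#' @param t_max horizon (in transitions) for basins of attraction.
#' @return object of class \code{"goal_spec"}.
#' @export
goal_spec <- function(gamma, chi = rep(FALSE, length(gamma)), t_max = 32L) {
  stopifnot(length(gamma) == length(chi))
  gamma <- gamma & !chi
  structure(list(gamma = gamma, chi = chi, t_max = as.integer(t_max)),
            class = "goal_spec")
}

## adjacency lists (successors / predecessors per state) from a count tensor
## or logical matrix, excluding transitions INTO costly states
.adj_from_b <- function(b, chi = NULL) {
  if (is.array(b) && length(dim(b)) == 3L) {
    m <- apply(b, c(1L, 2L), sum) > 0
  } else m <- b > 0
  if (!is.null(chi)) m[chi, ] <- FALSE
  S <- nrow(m)
  list(out = lapply(seq_len(S), function(j) which(m[, j])),
       into = lapply(seq_len(S), function(i) which(m[i, ])))
}

## breadth-first distances from a source set along an adjacency list
.bfs_dist <- function(adj, sources, horizon) {
  S <- length(adj)
  dist <- rep(Inf, S)
  dist[sources] <- 0
  frontier <- sources
  k <- 0L
  while (length(frontier) && k < horizon) {
    k <- k + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- k
    frontier <- nxt
  }
  dist
}

#' Backward-induction reachability plan
#'
#' Treats every non-zero transition probability as an edge, excludes costly
#' states, and computes for every state the minimum number of steps to any
#' goal state; the mask marks, for each horizon step k, the states exactly k
#' steps from goal.
#'
#' @param b_top transition count tensor (states x states x paths) or logical
#'   adjacency matrix (\code{[to, from]}).
#' @param goals a \code{\link{goal_spec}}.
#' @param horizon rollout depth (default 64).
#' @return object of class \code{"inductive_plan"}: \code{dist}
#'   (steps-to-goal per state, \code{Inf} if unreachable), \code{mask}
#'   (states x horizon logical) and \code{horizon}.
#' @export
inductive_mask <- function(b_top, goals, horizon = 64L) {
  stopifnot(horizon >= 1L, any(goals$gamma))
  adj <- .adj_from_b(b_top, chi = which(goals$chi))
  dist <- .bfs_dist(adj$into, which(goals$gamma), horizon)
  dist[goals$chi] <- Inf
  S <- length(dist)
  mask <- outer(dist, seq_len(horizon), "==")
  mask[is.na(mask)] <- FALSE
  structure(list(dist = dist, mask = mask, horizon = as.integer(horizon),
                 goals = goals),
            class = "inductive_plan")
}

#' Select a path by inductive inference
#'
#' Among the paths whose (most likely) successor strictly decreases the
#' distance to goal, picks the one whose successor has minimal distance,
#' breaking ties by the lowest path index.  If no path decreases the
#' distance, falls back to a softmax over negative expected free energy when
#' preferences are available, else signals no path.
#'
#' @param model a \code{\link{dgm}}.
#' @param state current state index (or posterior vector; its argmax is
#'   used).
#' @param plan an \code{\link{inductive_mask}} result.
#' @return list with \code{path} (index or \code{NA}), \code{successor} and
#'   \code{fallback} (logical: expected-free-energy prior was used).
#' @export
select_path <- function(model, state, plan) {
  if (length(state) > 1L) state <- which.max(state)
  succ <- vapply(seq_len(model$U),
                 function(u) which.max(model$B[, state, u]), 1L)
  real <- vapply(seq_len(model$U),
                 function(u) sum(model$B[, state, u]) > 0, NA)
  dd <- plan$dist[succ]
  dd[!real] <- Inf
  dcur <- plan$dist[state]
  ## from a goal state the strict-decrease requirement restarts towards the
  ## nearest other goal
  ok <- if (is.finite(dcur) && dcur == 0) which(is.finite(dd)) else
    which(is.finite(dd) & dd < dcur)
  if (length(ok)) {
    best <- ok[which.min(dd[ok])]        # which.min takes the first = lowest index
    return(list(path = best, successor = succ[best], fallback = FALSE))
  }
  if (!is.null(model$c)) {
    post <- list(s = matrix(as.numeric(seq_len(model$S) == state)), u = NULL)
    g <- vapply(which(real),
                function(u) expected_free_energy(model, post, u)$G, 0)
    p <- softmax(-g)
    pick <- which(real)[sample.int(length(p), 1L, prob = p)]
    return(list(path = pick, successor = succ[pick], fallback = TRUE))
  }
  list(path = NA_integer_, successor = NA_integer_, fallback = TRUE)
}

#' Select an action that realises a proprioceptive prediction
#'
#' Samples an action from a softmax (at high precision) of the predicted
#' probability of each action's proprioceptive consequence.
#'
#' @param prediction predicted probability vector over proprioceptive
#'   outcomes.
#' @param outcomes integer vector giving, per action, the outcome index that
#'   the action would realise.
#' @param precision softmax precision (default 512).
#' @param greedy logical; take the argmax instead of sampling.
#' @return the selected action index.
#' @export
select_action <- function(prediction, outcomes, precision = 512,
                          greedy = FALSE) {
  acc <- prediction[outcomes]
  p <- softmax(acc, precision)
  if (greedy) which.max(p) else sample.int(length(p), 1L, prob = p)
}
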