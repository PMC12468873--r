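#' Full run configuration for de novo learning
#'
#' Bundles the engine configuration with the three learning phases'
#' parameters.  Defaults are the study conditions used throughout: 10,000
#' random frames for structure learning with a group-size bound of 32 and
#' temporal decimation 2; 100-frame reward-gated epochs with basins of
#' attraction bounded at 32 transitions until 64 mutually reachable goal
#' states emerge; then 50 games of 200 frames of continual learning with a
#' 1/512 concentration parameter on transitions, action precision 512 and
#' inductive inference over 64 transitions.
#'
#' @param game a \code{\link{game_config}}.
#' @param frames random-play frames for structure learning.
#' @param max_group upper bound on the size of any modality group.
#' @param decimation temporal decimation factor between levels (a level-2
#'   generalised state spans \code{decimation} frames).
#' @param epoch_frames frames per reward-gated learning epoch (phase 2).
#' @param goal_threshold attractor learning stops once this many goal states
#'   are mutually reachable.
#' @param basin_horizon transition bound on the forward/backward orbits that
#'   define basins of attraction.
#' @param epoch_budget maximum number of 100-frame epochs played in phase 2.
#' @param games,game_frames continual-learning schedule (phase 3).
#' @param jitter concentration parameter added to transition tensors for
#'   continual learning.
#' @param action_precision softmax precision for action selection.
#' @param induction_horizon backward-induction rollout depth.
#' @param alpha precision of the expected-free-energy gate on Dirichlet
#'   updates (used by the optional per-step soft gate).
#' @param check_every attractor-core size is re-evaluated every this many
#'   assimilated epochs.
#' @param seed master seed; the game, policy and learning streams are derived
#'   from it.
#' @return a list of class \code{"denovo_config"}.
#' @export
denovo_config <- function(game = game_config(),
                          frames = 10000L, max_group = 32L, decimation = 2L,
                          epoch_frames = 100L, goal_threshold = 64L,
                          basin_horizon = 32L, epoch_budget = 6000L,
                          games = 50L, game_frames = 200L,
                          jitter = 1 / 512, action_precision = 512,
                          induction_horizon = 64L, alpha = 16,
                          check_every = 5L, seed = 1L) {
  stopifnot(frames > 0L, max_group > 0L, decimation > 1L,
            epoch_frames > 0L, goal_threshold > 0L, basin_horizon > 0L,
            epoch_budget > 0L, games > 0L, game_frames > 0L,
            jitter > 0, jitter < 1, action_precision > 0,
            induction_horizon >= 1L, alpha >= 0, check_every > 0L)
  cfg <- list(game = game, frames = as.integer(frames),
              max_group = as.integer(max_group),
              decimation = as.integer(decimation),
              epoch_frames = as.integer(epoch_frames),
              goal_threshold = as.integer(goal_threshold),
              basin_horizon = as.integer(basin_horizon),
              epoch_budget = as.integer(epoch_budget),
              games = as.integer(games), game_frames = as.integer(game_frames),
              jitter = jitter, action_precision = action_precision,
              induction_horizon = as.integer(induction_horizon),
              alpha = alpha, check_every = as.integer(check_every),
              seed = as.integer(seed))
  class(cfg) <- "denovo_config"
  cfg
}

## ---- growable key tables -------------------------------------------------
## A "tab" is an environment holding a character key vector plus parallel
## value vectors; batch lookup with optional insertion is a vectorised match.

.tab_new <- function(...) {
  e <- new.env(parent = emptyenv())
  e$keys <- character(0)
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

.tab_ids <- function(tab, keys, add = TRUE) {
  ids <- match(keys, tab$keys)
  if (add && anyNA(ids)) {
    tab$keys <- c(tab$keys, unique(keys[is.na(ids)]))
    ids <- match(keys, tab$keys)
  }
  ids
}

.tab_n <- function(tab) length(tab$keys)

.grow_to <- function(x, n, fill = 0) {
  if (length(x) < n) x <- c(x, rep(fill, n - length(x)))
  x
}

## Decode "a,b,c" keys back to integer vectors.
.key_decode <- function(keys) {
  lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
}

## ---- the model object ----------------------------------------------------
## A denovo_model is an environment (reference semantics are needed because
## the model grows online during play); user-facing phase functions clone it
## so their input is never mutated.

.factor_new <- function(channels, stream) {
  f <- .tab_new(counts = numeric(0))
  f$channels <- channels
  f$stream <- stream
  ## transitions: parallel vectors indexed by transition id
  f$tr <- .tab_new(from = integer(0), to = integer(0), slot = integer(0),
                   count = numeric(0))
  f$outdeg <- integer(0)
  f
}

.model_new <- function(config, layout) {
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$layout <- layout
  m$static <- integer(0)      # channel indices with no dynamics (no parent)
  m$static_sym <- integer(0)  # their constant symbol
  m$factors <- list()
  m$top <- NULL
  m$phase <- "empty"
  m$history <- list()
  class(m) <- "denovo_model"
  m
}

.top_new <- function() {
  t <- .tab_new(counts = numeric(0))
  t$cause_factor <- integer(0)  # which factor each cause channel reports
  t$cause_kind <- character(0)  # "state" or "path"
  t$tr <- .tab_new(from = integer(0), to = integer(0), slot = integer(0),
                   count = numeric(0))
  t$outdeg <- integer(0)
  t$d <- numeric(0)
  t$e <- numeric(0)
  t$goal <- logical(0)
  t$cost <- logical(0)
  t$active <- logical(0)
  t$n_states <- 0L
  t$id_map <- NULL             # pattern id -> merged state id, after merging
  t$rep_keys <- NULL           # representative pattern per merged state
  t$members <- NULL
  t
}

.model_clone <- function(m) {
  m2 <- new.env(parent = emptyenv())
  for (nm in ls(m, all.names = TRUE)) {
    v <- get(nm, envir = m)
    assign(nm, v, envir = m2)
  }
  clone_tab <- function(tb) {
    e <- new.env(parent = emptyenv())
    for (nm in ls(tb, all.names = TRUE)) {
      v <- get(nm, envir = tb)
      assign(nm, if (is.environment(v)) clone_tab(v) else v, envir = e)
    }
    e
  }
  m2$factors <- lapply(m$factors, clone_tab)
  if (!is.null(m$top)) m2$top <- clone_tab(m$top)
  class(m2) <- "denovo_model"
  m2
}

#' Number of hierarchical levels of a model
#' @param model a \code{denovo_model}.
#' @return integer level count.
#' @export
n_levels <- function(model) {
  if (!length(model$factors)) return(0L)
  if (is.null(model$top)) 1L else 2L
}

#' Number of path slots of the top-level transition tensor
#' @param model a \code{denovo_model}.
#' @return integer: the third dimension of the highest-level transition
#'   tensor (the maximum out-degree over generalised states).
#' @export
n_paths <- function(model) {
  if (is.null(model$top) || !length(model$top$tr$slot)) return(0L)
  max(model$top$tr$slot)
}

#' @export
print.denovo_model <- function(x, ...) {
  cat(sprintf("de novo generative model (%s phase)\n", x$phase))
  cat(sprintf("  levels: %d | level-1 factors: %d (+%d static channels)\n",
              n_levels(x), length(x$factors), length(x$static)))
  if (!is.null(x$top)) {
    act <- sum(x$top$active)
    cat(sprintf("  generalised states: %d active / %d discovered | paths: %d\n",
                act, .tab_n(x$top), n_paths(x)))
    if (length(x$top$goal))
      cat(sprintf("  goal states: %d | costly states: %d\n",
                  sum(x$top$goal & x$top$active), sum(x$top$cost & x$top$active)))
  }
  invisible(x)
}

#' @export
summary.denovo_model <- function(object, ...) {
  out <- list(phase = object$phase,
              levels = n_levels(object),
              n_factors = length(object$factors),
              n_static = length(object$static),
              factor_states = vapply(object$factors, .tab_n, 1L),
              factor_streams = vapply(object$factors, function(f) f$stream, ""),
              n_states = if (is.null(object$top)) NA_integer_ else .tab_n(object$top),
              n_active = if (is.null(object$top)) NA_integer_ else sum(object$top$active),
              n_paths = n_paths(object),
              n_goals = if (is.null(object$top)) NA_integer_ else
                sum(object$top$goal & object$top$active))
  class(out) <- "summary.denovo_model"
  out
}

#' @export
print.summary.denovo_model <- function(x, ...) {
  cat(sprintf("phase %s: %d level(s), %d factors (%d static channels)\n",
              x$phase, x$levels, x$n_factors, x$n_static))
  if (!is.na(x$n_states))
    cat(sprintf("states %d (%d active), paths %d, goals %d\n",
                x$n_states, x$n_active, x$n_paths, x$n_goals))
  tab <- table(x$factor_streams)
  cat("factors per stream:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
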