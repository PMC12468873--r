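#' Mutual-information matrix of observation channels
#'
#' Plug-in mutual information between every pair of categorical channels,
#' estimated from their empirical joint over a sequence of frames.  The
#' diagonal holds each channel's empirical entropy, so constant channels have
#' an all-zero row and column.
#'
#' @param obs integer matrix, channels x frames (symbols coded from 1).
#' @param sizes optional per-channel alphabet sizes (defaults to the observed
#'   maxima).
#' @return symmetric non-negative matrix in nats.
#' @export
mutual_info_matrix <- function(obs, sizes = NULL) {
  if (ncol(obs) < 2L) stop("need at least 2 frames")
  n <- nrow(obs)
  Tn <- ncol(obs)
  if (is.null(sizes)) sizes <- apply(obs, 1L, max)
  ent <- function(counts) {
    p <- counts[counts > 0] / Tn
    -sum(p * log(p))
  }
  H <- vapply(seq_len(n), function(i) ent(tabulate(obs[i, ], sizes[i])), 0)
  omega <- matrix(0, n, n)
  diag(omega) <- H
  live <- which(H > 0)
  if (length(live) > 1L) {
    for (ii in seq_along(live)[-length(live)]) {
      i <- live[ii]
      xi <- obs[i, ]
      for (j in live[(ii + 1L):length(live)]) {
        code <- (xi - 1L) * sizes[j] + obs[j, ]
        Hij <- ent(tabulate(code, sizes[i] * sizes[j]))
        mi <- max(H[i] + H[j] - Hij, 0)
        omega[i, j] <- omega[j, i] <- mi
      }
    }
  }
  omega
}

#' Spectral partition of channels into dependency groups
#'
#' Repeatedly extracts the principal group from a non-negative symmetric
#' dependency matrix: the channels whose loading on the principal eigenvector
#' is at least half the maximum loading (capped at \code{max_size} by taking
#' the top loadings), which are then removed before the next extraction,
#' until every channel has been assigned.
#'
#' @param omega symmetric non-negative matrix (e.g. from
#'   \code{\link{mutual_info_matrix}}).
#' @param max_size upper bound on group size.
#' @return list of integer vectors, each a group of channel indices.
#' @export
spectral_partition <- function(omega, max_size = 32L) {
  stopifnot(nrow(omega) == ncol(omega))
  rem <- seq_len(nrow(omega))
  groups <- list()
  while (length(rem)) {
    if (length(rem) == 1L) {
      groups[[length(groups) + 1L]] <- rem
      break
    }
    sub <- omega[rem, rem]
    v <- abs(eigen(sub, symmetric = TRUE)$vectors[, 1L])
    mem <- which(v >= 0.5 * max(v))
    if (length(mem) > max_size)
      mem <- mem[order(v[mem], decreasing = TRUE)[seq_len(max_size)]]
    groups[[length(groups) + 1L]] <- sort(rem[mem])
    rem <- rem[-mem]
  }
  groups
}

#' Losslessly compress a grouped observation sequence into states
#'
#' Concatenates the group's channels per frame into one column and maps each
#' distinct column to a state; the Dirichlet likelihood column of state k is
#' its one-hot pattern scaled by its number of occurrences, so argmax
#' reconstruction of every frame is exact.
#'
#' @param obs integer matrix (group channels x frames).
#' @param sizes per-channel alphabet sizes (defaults to observed maxima).
#' @return list with \code{a} (concatenated-one-hot likelihood counts,
#'   \code{sum(sizes)} x K), \code{states} (state id per frame),
#'   \code{patterns} (list of symbol vectors per state) and \code{static}
#'   (logical: a single state, i.e. no dynamics).
#' @export
compress_group <- function(obs, sizes = NULL) {
  if (!is.matrix(obs)) obs <- matrix(obs, 1L)
  if (!ncol(obs)) stop("empty sequence")
  if (is.null(sizes)) sizes <- apply(obs, 1L, max)
  keys <- if (nrow(obs) == 1L) as.character(obs[1L, ]) else
    do.call(paste, c(lapply(seq_len(nrow(obs)), function(i) obs[i, ]), sep = ","))
  uk <- unique(keys)
  states <- match(keys, uk)
  K <- length(uk)
  counts <- tabulate(states, K)
  patterns <- lapply(strsplit(uk, ",", fixed = TRUE), as.integer)
  offs <- c(0L, cumsum(sizes))
  a <- matrix(0, sum(sizes), K)
  for (k in seq_len(K))
    a[offs[seq_len(nrow(obs))] + patterns[[k]], k] <- counts[k]
  list(a = a, states = states, patterns = patterns, static = K == 1L)
}

#' Accumulate unique transitions into a transition tensor
#'
#' Each observed bigram (s to s') is recorded once per path slot: if s' is
#' already recorded under some slot for source s it is incremented, otherwise
#' it occupies the lowest slot with an empty source-s column, growing the
#' path dimension as needed.  The number of paths therefore equals the
#' maximum observed out-degree.
#'
#' @param states integer state sequence (length >= 2).
#' @param n_states optional number of states (defaults to max observed).
#' @return 3-d count array, states x states x paths, where entry
#'   \code{[to, from, path]} counts occurrences.
#' @export
accumulate_transitions <- function(states, n_states = NULL) {
  if (length(states) < 2L) stop("state sequence too short")
  if (is.null(n_states)) n_states <- max(states)
  from <- states[-length(states)]
  to <- states[-1L]
  key <- paste(from, to)
  uk <- unique(key)
  tid <- match(key, uk)
  ufrom <- from[match(uk, key)]
  uto <- to[match(uk, key)]
  outdeg <- integer(n_states)
  slot <- integer(length(uk))
  for (i in seq_along(uk)) {           # in order of first appearance
    outdeg[ufrom[i]] <- outdeg[ufrom[i]] + 1L
    slot[i] <- outdeg[ufrom[i]]
  }
  b <- array(0, c(n_states, n_states, max(slot)))
  cnt <- tabulate(tid, length(uk))
  b[cbind(uto, ufrom, slot)] <- cnt
  b
}

## ---- internal batch assimilation ----------------------------------------
## Shared by all phases: map a frame window onto level-1 factor states,
## per-epoch causes and top-level generalised states, optionally
## accumulating Dirichlet counts.

.factor_frame_keys <- function(obs, channels) {
  if (length(channels) == 1L) as.character(obs[channels, ]) else
    do.call(paste, c(lapply(channels, function(ch) obs[ch, ]), sep = ","))
}

## assign slots to newly created transition ids (rows of tr with slot 0)
.assign_slots <- function(tr, tids) {
  need <- max(tids)
  tr$from <- .grow_to(tr$from, need, 0L)
  tr$to <- .grow_to(tr$to, need, 0L)
  tr$slot <- .grow_to(tr$slot, need, 0L)
  tr$count <- .grow_to(tr$count, need, 0)
  tr
}

## Process one window of frames.  Returns the per-epoch top-state ids.
.assimilate_window <- function(model, obs, count = TRUE, prev_top = NA_integer_) {
  dec <- model$config$decimation
  Tn <- ncol(obs)
  nE <- Tn %/% dec
  if (nE < 1L) stop("window shorter than one epoch")
  obs <- obs[, seq_len(nE * dec), drop = FALSE]
  Fh <- length(model$factors)
  causes <- matrix(0L, 2L * Fh, nE)
  for (fi in seq_len(Fh)) {
    f <- model$factors[[fi]]
    keys <- .factor_frame_keys(obs, f$channels)
    ids <- .tab_ids(f, keys)
    n <- .tab_n(f)
    f$counts <- .grow_to(f$counts, n)
    f$outdeg <- .grow_to(f$outdeg, n, 0L)
    if (count) f$counts <- f$counts + tabulate(ids, n)
    ## within-epoch transitions define this factor's paths
    em <- matrix(ids, dec)
    from <- em[1L, ]
    slots <- integer(nE)
    for (step in 2L:dec) {
      to <- em[step, ]
      tkeys <- paste(em[step - 1L, ], to)
      tids <- .tab_ids(f$tr, tkeys)
      f$tr <- .assign_slots(f$tr, tids)
      new <- which(f$tr$slot[tids] == 0L)
      if (length(new)) {
        for (j in unique(tids[new])) {
          src <- em[step - 1L, which(tids == j)[1L]]
          f$outdeg[src] <- f$outdeg[src] + 1L
          f$tr$from[j] <- src
          f$tr$to[j] <- to[which(tids == j)[1L]]
          f$tr$slot[j] <- f$outdeg[src]
        }
      }
      if (count) {
        inc <- tabulate(tids, length(f$tr$count))
        f$tr$count <- f$tr$count + inc
      }
      if (step == 2L) slots <- f$tr$slot[tids]
    }
    causes[2L * fi - 1L, ] <- from
    causes[2L * fi, ] <- slots
  }
  ## top level: one generalised state per epoch
  top <- model$top
  tkeys <- do.call(paste, c(lapply(seq_len(nrow(causes)), function(i) causes[i, ]),
                            sep = ","))
  ids <- .tab_ids(top, tkeys)
  n <- .tab_n(top)
  top$n_states <- n
  if (length(top$counts) < n) {
    old <- length(top$counts)
    top$counts <- .grow_to(top$counts, n)
    top$d <- .grow_to(top$d, n)
    top$outdeg <- .grow_to(top$outdeg, n, 0L)
    top$active <- .grow_to(top$active, n, TRUE)
    top$goal <- .grow_to(top$goal, n, FALSE)
    top$cost <- .grow_to(top$cost, n, FALSE)
    .mark_goal_cost(model, (old + 1L):n)
  }
  if (count) {
    top$counts <- top$counts + tabulate(ids, n)
    top$active[ids] <- TRUE      # re-encountered states re-enter the model
    if (is.na(prev_top)) top$d[ids[1L]] <- top$d[ids[1L]] + 1
  }
  seqs <- if (!is.na(prev_top)) c(prev_top, ids) else ids
  if (length(seqs) > 1L) {
    from <- seqs[-length(seqs)]
    to <- seqs[-1L]
    tkeys2 <- paste(from, to)
    tids <- .tab_ids(top$tr, tkeys2)
    top$tr <- .assign_slots(top$tr, tids)
    new <- which(top$tr$slot[tids] == 0L)
    if (length(new)) {
      for (j in unique(tids[new])) {
        k <- which(tids == j)[1L]
        top$outdeg[from[k]] <- top$outdeg[from[k]] + 1L
        top$tr$from[j] <- from[k]
        top$tr$to[j] <- to[k]
        top$tr$slot[j] <- top$outdeg[from[k]]
      }
    }
    if (count) {
      top$tr$count <- top$tr$count + tabulate(tids, length(top$tr$count))
      top$e <- .grow_to(top$e, max(top$tr$slot))
      sl <- top$tr$slot[tids]
      top$e <- top$e + tabulate(sl, length(top$e))
    }
  }
  ids
}

## goal/cost marks for newly created generalised states, from the reward and
## punishment cause channels of their defining pattern
.mark_goal_cost <- function(model, new_ids) {
  top <- model$top
  ri <- which(vapply(model$factors, function(f) f$stream, "") == "reward")
  pi_ <- which(vapply(model$factors, function(f) f$stream, "") == "punishment")
  pats <- .key_decode(top$keys[new_ids])
  sym_over_epoch <- function(fi, pat) {
    f <- model$factors[[fi]]
    s0 <- pat[2L * fi - 1L]
    u <- pat[2L * fi]
    syms <- as.integer(f$keys[s0])
    nxt <- f$tr$to[f$tr$from == s0 & f$tr$slot == u]
    if (length(nxt)) syms <- c(syms, as.integer(f$keys[nxt[1L]]))
    syms
  }
  for (i in seq_along(new_ids)) {
    id <- new_ids[i]
    pat <- pats[[i]]
    g <- length(ri) && any(sym_over_epoch(ri, pat) == 2L)
    x <- length(pi_) && any(sym_over_epoch(pi_, pat) == 2L)
    top$cost[id] <- x
    top$goal[id] <- g && !x    # costliness takes precedence
  }
  invisible(NULL)
}

#' Learn the structure of a hierarchical generative model from observations
#'
#' Phase-1 renormalising structure learning: channels with no dynamics are
#' set aside (they receive no parent); the remaining channels are grouped by
#' spectral partitioning of their mutual information, stream by stream; each
#' group is compressed losslessly into a factor of unique states whose
#' transitions define paths; per-epoch hidden causes (the initial state and
#' path of every factor, decimated in time) are then compressed jointly into
#' a single final-level factor of generalised states with its own transition
#' tensor.
#'
#' @param obs integer observation matrix (channels x frames) such as
#'   \code{play_frames()$obs}.
#' @param config a \code{\link{denovo_config}}; its \code{max_group} and
#'   \code{decimation} entries control the grouping bound and the temporal
#'   decimation between levels.
#' @param layout an \code{\link{obs_layout}} describing channel alphabets and
#'   streams.
#' @return a \code{denovo_model} with populated Dirichlet count tensors.
#' @export
learn_structure <- function(obs, config = denovo_config(),
                            layout = obs_layout(config$game)) {
  stopifnot(nrow(obs) == layout$n_channels, ncol(obs) >= 2L)
  model <- .model_new(config, layout)
  nch <- nrow(obs)
  varying <- vapply(seq_len(nch), function(i) length(unique(obs[i, ])) > 1L,
                    NA)
  model$static <- which(!varying)
  model$static_sym <- obs[!varying, 1L]
  groups <- list()
  streams <- character(0)
  for (s in unique(layout$streams)) {
    chs <- which(layout$streams == s & varying)
    if (!length(chs)) next
    gs <- if (length(chs) == 1L) list(chs) else {
      om <- mutual_info_matrix(obs[chs, , drop = FALSE], layout$sizes[chs])
      lapply(spectral_partition(om, config$max_group), function(g) chs[g])
    }
    groups <- c(groups, gs)
    streams <- c(streams, rep(s, length(gs)))
  }
  if (!length(groups)) {
    model$phase <- "degenerate"
    warning("all channels are static: degenerate single-state model")
    return(model)
  }
  model$factors <- lapply(seq_along(groups),
                          function(i) .factor_new(groups[[i]], streams[i]))
  model$top <- .top_new()
  .assimilate_window(model, obs, count = TRUE)
  model$phase <- "structure"
  model
}

#' Empty a model's Dirichlet counts, keeping its structure
#'
#' Returns a skeleton retaining the channel grouping, stream labels and
#' parent structure discovered in phase 1, with all state dictionaries and
#' count tensors emptied, ready for reward-gated growth.
#'
#' @param model a \code{denovo_model}.
#' @return a new skeleton \code{denovo_model}.
#' @export
empty_counts <- function(model) {
  m <- .model_clone(model)
  m$factors <- lapply(model$factors,
                      function(f) .factor_new(f$channels, f$stream))
  m$top <- .top_new()
  m$phase <- "skeleton"
  m
}
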