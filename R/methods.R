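## decode a generalised state into its two frames of channel symbols
.decode_state_frames <- function(model, id) {
  pat <- .state_pattern(model, id)
  lay <- model$layout
  out <- matrix(NA_integer_, lay$n_channels, 2L)
  if (length(model$static))
    out[model$static, ] <- model$static_sym
  for (fi in seq_along(model$factors)) {
    f <- model$factors[[fi]]
    s0 <- pat[2L * fi - 1L]
    u <- pat[2L * fi]
    p1 <- as.integer(strsplit(f$keys[s0], ",", fixed = TRUE)[[1L]])
    nxt <- f$tr$to[f$tr$from == s0 & f$tr$slot == u]
    p2 <- if (length(nxt))
      as.integer(strsplit(f$keys[nxt[1L]], ",", fixed = TRUE)[[1L]]) else p1
    out[f$channels, 1L] <- p1
    out[f$channels, 2L] <- p2
  }
  out
}

#' Replay an observation stream through a model
#'
#' Identifies the generalised state of every epoch of a recorded stream and
#' reconstructs the frames from the model's likelihood mappings by argmax
#' decoding.  On its own training stream a phase-1 model reconstructs every
#' frame exactly (lossless compression).
#'
#' @param model a \code{denovo_model}.
#' @param obs integer observation matrix (channels x frames).
#' @return list with \code{obs_hat} (reconstructed symbols; \code{NA} where
#'   an epoch was not recognised), \code{states} (epoch state ids) and
#'   \code{exact} (logical: reconstruction matches everywhere).
#' @export
replay_epochs <- function(model, obs) {
  dec <- model$config$decimation
  nE <- ncol(obs) %/% dec
  obs <- obs[, seq_len(nE * dec), drop = FALSE]
  hat <- matrix(NA_integer_, nrow(obs), ncol(obs))
  ids <- integer(nE)
  for (k in seq_len(nE)) {
    w <- obs[, (dec * (k - 1L) + 1L):(dec * k), drop = FALSE]
    id <- .identify_epoch(model, w)
    ids[k] <- id
    if (!is.na(id))
      hat[, (dec * (k - 1L) + 1L):(dec * k)] <- .decode_state_frames(model, id)
  }
  list(obs_hat = hat, states = ids,
       exact = !anyNA(hat) && all(hat == obs))
}

#' Generate observations from the model
#'
#' Rolls the top-level transition tensor forward from a sampled initial
#' generalised state, sampling successors from the (jitter-free) normalised
#' transition counts, and decodes each state into its frames of channel
#' symbols.
#'
#' @param object a trained \code{denovo_model}.
#' @param nsim number of frames to generate.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return integer symbol matrix (channels x nsim).
#' @export
simulate.denovo_model <- function(object, nsim = 100L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  top <- object$top
  act <- which(top$active)
  if (!length(act)) stop("model has no active states")
  dw <- top$d[act]
  cur <- if (sum(dw) > 0) act[sample.int(length(act), 1L, prob = dw)] else
    act[sample.int(length(act), 1L)]
  sx <- .succ_index(object)
  dec <- object$config$decimation
  nE <- ceiling(nsim / dec)
  out <- matrix(NA_integer_, object$layout$n_channels, nE * dec)
  for (k in seq_len(nE)) {
    out[, (dec * (k - 1L) + 1L):(dec * k)] <- .decode_state_frames(object, cur)
    succ <- sx$succ[[cur]]
    if (is.null(succ) || !length(succ)) {
      cur <- act[sample.int(length(act), 1L)]   # uniform over other states
    } else {
      w <- sx$counts[[cur]]
      cur <- succ[sample.int(length(succ), 1L, prob = w)]
    }
  }
  out[, seq_len(nsim), drop = FALSE]
}

#' Predictive distribution over successor states and outcomes
#'
#' @param object a trained \code{denovo_model}.
#' @param state a generalised state id (e.g. from \code{\link{replay_epochs}}).
#' @param steps number of top-level transitions to roll forward.
#' @param ... unused.
#' @return list with \code{states} (named probability vector over reachable
#'   states after \code{steps}) and \code{frames} (expected channel symbols
#'   of the most probable state).
#' @export
predict.denovo_model <- function(object, state, steps = 1L, ...) {
  stopifnot(steps >= 1L)
  top <- object$top
  jit <- object$config$jitter
  sx <- .succ_index(object)
  p <- stats::setNames(1, state)
  for (k in seq_len(steps)) {
    nxt <- numeric(0)
    for (i in seq_along(p)) {
      s <- as.integer(names(p)[i])
      succ <- if (s <= length(sx$succ)) sx$succ[[s]] else integer(0)
      if (is.null(succ) || !length(succ)) next
      w <- sx$counts[[s]] + jit
      w <- p[i] * w / sum(w)
      for (j in seq_along(succ)) {
        nm <- as.character(succ[j])
        nxt[nm] <- (if (nm %in% names(nxt)) nxt[nm] else 0) + w[j]
      }
    }
    if (!length(nxt)) break
    p <- nxt / sum(nxt)
  }
  best <- as.integer(names(p)[which.max(p)])
  list(states = p, frames = .decode_state_frames(object, best))
}

#' Plot learning curves and the discovered transition structure
#'
#' Shows, as available: state/path growth and goal-core size over attractor
#' learning, per-game rewards/losses and the evidence-bound path integral
#' over continual learning, and the goal-state adjacency matrix.
#'
#' @param x a \code{denovo_model}.
#' @param ... passed to \code{par}.
#' @export
plot.denovo_model <- function(x, ...) {
  ha <- x$history$attractor
  hc <- x$history$continual
  panels <- sum(!is.null(ha), !is.null(hc)) * 2L
  if (!panels) stop("no learning history to plot")
  op <- graphics::par(mfrow = c(panels %/% 2L, 2L), mar = c(4, 4, 2, 1), ...)
  on.exit(graphics::par(op))
  if (!is.null(ha)) {
    graphics::plot(ha$assimilated, ha$states, type = "l",
                   xlab = "assimilated epochs", ylab = "generalised states",
                   main = "attractor learning")
    graphics::lines(ha$assimilated, ha$paths * max(ha$states) / 10,
                    lty = 2)
    graphics::plot(ha$assimilated, ha$goals, type = "l",
                   xlab = "assimilated epochs", ylab = "goal states",
                   main = "goal discovery")
    graphics::lines(ha$assimilated, ha$core, lty = 2)
    graphics::legend("topleft", c("goals", "mutually reachable"),
                     lty = 1:2, bty = "n")
  }
  if (!is.null(hc)) {
    graphics::plot(hc$game, hc$rewards, type = "h", ylim = c(0, max(hc$rewards)),
                   xlab = "game", ylab = "count", main = "continual learning")
    graphics::points(hc$game, hc$losses, pch = 4)
    graphics::legend("bottomright", c("rewards", "losses"),
                     pch = c(NA, 4), lty = c(1, NA), bty = "n")
    graphics::plot(hc$game, hc$elbo, type = "l", xlab = "game",
                   ylab = "ELBO path integral (nats)",
                   main = "evidence bound")
  }
  invisible(x)
}
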