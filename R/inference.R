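#' Construct a dense single-level generalised POMDP
#'
#' A small, fully dense discrete generative model: per-modality likelihood
#' count matrices, a state transition count tensor indexed by path, priors
#' over initial states and paths, and optional preference counts per
#' modality.  Used for exact filtering, planning and learning at desk scale;
#' the hierarchical game model composes levels of this form.
#'
#' @param A list of likelihood count matrices (outcomes x states).
#' @param B transition count array (states x states x paths), column
#'   convention \code{B[to, from, path]}.
#' @param d initial-state prior counts (length states).
#' @param e path prior counts (length paths).
#' @param c optional list of preference counts over outcomes per modality.
#' @return an object of class \code{"dgm"}.
#' @export
dgm <- function(A, B, d = NULL, e = NULL, c = NULL) {
  if (is.matrix(B)) B <- array(B, c(dim(B), 1L))
  S <- dim(B)[1L]
  stopifnot(dim(B)[2L] == S,
            all(vapply(A, ncol, 1L) == S),
            all(unlist(A) >= 0), all(B >= 0))
  if (is.null(d)) d <- rep(1, S)
  if (is.null(e)) e <- rep(1, dim(B)[3L])
  stopifnot(length(d) == S, length(e) == dim(B)[3L])
  if (!is.null(c)) stopifnot(length(c) == length(A))
  structure(list(A = A, B = B, d = d, e = e, c = c,
                 S = S, U = dim(B)[3L], G = length(A)),
            class = "dgm")
}

.obs_vec <- function(o, size) {
  if (length(o) == 1L && o == round(o) && o >= 1) {
    v <- numeric(size)
    v[o] <- 1
    v
  } else o
}

.log_floor <- function(p) log(pmax(p, exp(-32)))

#' Posterior over hidden states given one observation
#'
#' Combines ascending likelihood messages with the log prior through a
#' softmax: the exact Bayesian posterior when the model's likelihoods are
#' taken at their normalised expectations.
#'
#' @param model a \code{\link{dgm}}.
#' @param obs list with one entry per modality: a one-hot/soft outcome vector
#'   or an outcome index.
#' @param prior normalised prior over states.
#' @return posterior probability vector over states.
#' @export
state_posterior <- function(model, obs, prior = normalise_columns(model$d)) {
  stopifnot(length(obs) == model$G, length(prior) == model$S)
  msg <- .log_floor(prior)
  for (g in seq_len(model$G)) {
    o <- .obs_vec(obs[[g]], nrow(model$A[[g]]))
    if (length(o) != nrow(model$A[[g]])) stop("observation dimension mismatch")
    msg <- msg + as.vector(crossprod(.log_floor(normalise_columns(model$A[[g]])), o))
  }
  softmax(msg)
}

#' Exact forward filtering over one epoch
#'
#' Runs the exact forward algorithm jointly over hidden states and the
#' (fixed-within-epoch) path, which coincides with the fixed points of the
#' variational updates when backward messages are omitted.  Per-step log
#' normalisers are returned as the evidence-bound contributions; their sum is
#' the exact log marginal likelihood of the epoch.
#'
#' @param model a \code{\link{dgm}}.
#' @param obs_seq list of observations (each as in
#'   \code{\link{state_posterior}}).
#' @return object of class \code{"denovo_posterior"}: \code{s} (states x
#'   time marginals), \code{u} (path posterior), \code{F} (per-step
#'   evidence-bound contributions, nats).
#' @export
filter_epoch <- function(model, obs_seq) {
  Tn <- length(obs_seq)
  if (!Tn) stop("empty observation sequence")
  Ab <- lapply(model$A, normalise_columns)
  Bb <- normalise_columns(model$B)
  lik <- function(obs) {
    l <- rep(1, model$S)
    for (g in seq_len(model$G)) {
      o <- .obs_vec(obs[[g]], nrow(Ab[[g]]))
      l <- l * as.vector(crossprod(Ab[[g]], o))
    }
    l
  }
  alpha <- outer(normalise_columns(model$d) * lik(obs_seq[[1L]]),
                 normalise_columns(model$e))
  Fs <- numeric(Tn)
  Fs[1L] <- log(sum(alpha))
  alpha <- alpha / sum(alpha)
  smarg <- matrix(0, model$S, Tn)
  smarg[, 1L] <- rowSums(alpha)
  if (Tn > 1L) for (t in 2L:Tn) {
    for (u in seq_len(model$U))
      alpha[, u] <- Bb[, , u] %*% alpha[, u]
    alpha <- alpha * lik(obs_seq[[t]])
    Fs[t] <- log(sum(alpha))
    alpha <- alpha / sum(alpha)
    smarg[, t] <- rowSums(alpha)
  }
  structure(list(s = smarg, u = colSums(alpha), F = Fs),
            class = "denovo_posterior")
}

#' Predictive posterior over states and outcomes
#'
#' Rolls the transition tensor forward under the expected path and maps the
#' result through the likelihoods to outcome space.
#'
#' @param model a \code{\link{dgm}}.
#' @param posterior a \code{"denovo_posterior"} from
#'   \code{\link{filter_epoch}} (or a list with \code{s} and \code{u}).
#' @param steps non-negative number of transitions to roll forward
#'   (\code{0} predicts outcomes at the current time).
#' @return list with \code{states} (predicted state distribution) and
#'   \code{outcomes} (list of predicted outcome distributions per modality).
#' @export
predictive_posterior <- function(model, posterior, steps = 1L) {
  if (steps < 0L) stop("steps must be >= 0")
  q <- posterior$s[, ncol(posterior$s)]
  u <- posterior$u
  Bb <- normalise_columns(model$B)
  if (steps > 0L) for (k in seq_len(steps)) {
    qn <- numeric(model$S)
    for (j in seq_len(model$U)) qn <- qn + u[j] * (Bb[, , j] %*% q)
    q <- as.vector(qn)
  }
  list(states = q,
       outcomes = lapply(model$A, function(a) as.vector(normalise_columns(a) %*% q)))
}

#' Evidence lower bound of an observation sequence
#'
#' @param model a \code{\link{dgm}}.
#' @param obs_seq list of observations.
#' @return numeric vector of per-step contributions (nats); their sum equals
#'   the exact log marginal likelihood for this single-factor model.
#' @export
elbo <- function(model, obs_seq) {
  filter_epoch(model, obs_seq)$F
}
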