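#' Accumulate Dirichlet counts from posterior expectations
#'
#' Adds the outer product of an outcome expectation with the (product of)
#' parent-state expectations to a likelihood count tensor.
#'
#' @param a count matrix (outcomes x states) or array.
#' @param o outcome expectation (sums to 1).
#' @param s parent-state expectation vector, or list of vectors for several
#'   parent factors (their outer product is used).
#' @return updated count tensor, same shape as \code{a}.
#' @export
accumulate_counts <- function(a, o, s) {
  if (is.list(s)) s <- Reduce(function(x, y) as.vector(outer(x, y)), s)
  da <- outer(o, s)
  if (!all(dim(a) == dim(da))) stop("dimension mismatch between a and o x s")
  a + da
}

#' Expected-free-energy-gated Dirichlet update
#'
#' Treats committing to a count update as an action: the probability of
#' committing is a softmax (at precision \code{alpha}) of the negative
#' expected free energies of the parameters without and with the update, and
#' the returned counts are the ensuing Bayesian model average.
#'
#' @param a current count matrix.
#' @param da proposed increment (non-negative).
#' @param c preference counts over outcomes.
#' @param alpha gate precision; \code{0} gives an ungated half update, large
#'   values give Bayesian model selection.
#' @return list with \code{a} (updated counts), \code{p_commit}, \code{G0}
#'   and \code{G1}.
#' @export
active_update <- function(a, da, c, alpha = 16) {
  stopifnot(alpha >= 0, all(da >= 0))
  G0 <- parameter_efe(a, c)
  G1 <- parameter_efe(a + da, c)
  p <- if (is.infinite(G0) && is.infinite(G1)) 0.5 else
    softmax(-c(G0, G1), alpha)[2L]
  list(a = a + p * da, p_commit = p, G0 = G0, G1 = G1)
}

.log_beta_cols <- function(a) {
  m <- if (is.null(dim(a))) matrix(a) else matrix(a, dim(a)[1L])
  sum(lgamma(m)) - sum(lgamma(colSums(m)))
}

#' Bayesian model reduction for Dirichlet counts
#'
#' Scores a reduced prior against a model's posterior analytically through
#' ratios of Dirichlet normalising constants (multivariate beta functions,
#' applied per column and summed in log space), and returns the posterior
#' that would have been obtained under the reduced prior.
#'
#' @param a_post posterior counts.
#' @param a_prior prior counts (same shape).
#' @param a_reduced_prior reduced prior counts (same shape).
#' @return list with \code{delta_f} (the change in variational free energy,
#'   nats; positive favours the reduced model) and \code{a_reduced}
#'   (the reduced posterior counts).
#' @export
bmr_delta_f <- function(a_post, a_prior, a_reduced_prior) {
  stopifnot(all(dim(a_post) == dim(a_prior)),
            all(dim(a_post) == dim(a_reduced_prior)))
  a_red <- a_post + a_reduced_prior - a_prior
  m <- if (is.null(dim(a_red))) matrix(a_red) else matrix(a_red, dim(a_red)[1L])
  if (any(colSums(m) <= 0)) stop("non-positive reduced-posterior column sum")
  if (any(a_red < 0)) stop("reduced posterior has negative counts")
  df <- .log_beta_cols(a_post) + .log_beta_cols(a_reduced_prior) -
    .log_beta_cols(a_prior) - .log_beta_cols(a_red)
  list(delta_f = df, a_reduced = a_red)
}

#' Log odds for retaining a parent model over an augmented model
#'
#' Combines the difference in (variational bounds on) log evidence with the
#' difference in expected free energy of the parameters, as a log Bayes
#' factor: positive values favour retaining the parent.
#'
#' @param f_parent,f_augmented log evidence bounds (nats).
#' @param g_parent,g_augmented parameter expected free energies (nats).
#' @return log odds ratio (parent over augmented).
#' @export
compare_models <- function(f_parent, g_parent, f_augmented, g_augmented) {
  (f_parent - f_augmented) + (g_augmented - g_parent)
}
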