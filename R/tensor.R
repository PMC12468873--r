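#' Column-wise normalisation of a count tensor
#'
#' Normalises each column (the leading dimension, for every combination of
#' trailing indices) of a non-negative count array to a categorical
#' distribution.  All-zero columns map to the uniform distribution, so that
#' states with no recorded successors transition anywhere with equal
#' probability.
#'
#' @param a non-negative numeric vector, matrix or 3-d array of Dirichlet
#'   counts.
#' @return array of the same shape whose columns each sum to one.
#' @export
normalise_columns <- function(a) {
  if (any(a < 0)) stop("negative counts are not allowed")
  d <- dim(a)
  if (is.null(d)) {
    s <- sum(a)
    return(if (s == 0) rep(1 / length(a), length(a)) else a / s)
  }
  m <- if (length(d) == 2L) a else matrix(a, d[1L])
  cs <- colSums(m)
  zero <- cs == 0
  cs[zero] <- 1
  m <- sweep(m, 2L, cs, "/")
  if (any(zero)) m[, zero] <- 1 / d[1L]
  array(m, d)
}

#' Expected log-probabilities under a Dirichlet
#'
#' Returns \code{digamma(a) - digamma(colSums(a))} column-wise: the
#' expectation of the log categorical parameters under the Dirichlet with
#' counts \code{a}.  Counts are floored at \code{1e-16} so that structural
#' zeros yield a large negative (rather than undefined) expected log.
#'
#' @param a count vector, matrix or 3-d array with strictly positive column
#'   sums.
#' @return array of expected logs, same shape as \code{a}.
#' @export
expected_log <- function(a) {
  if (any(a < 0)) stop("negative counts are not allowed")
  d <- dim(a)
  m <- if (is.null(d)) matrix(a) else matrix(a, d[1L])
  if (any(colSums(m) <= 0)) stop("all-zero column: expected log undefined")
  m <- pmax(m, 1e-16)
  out <- digamma(m) - rep(digamma(colSums(m)), each = nrow(m))
  if (is.null(d)) as.vector(out) else array(out, d)
}

#' Stabilised softmax
#'
#' @param v finite numeric vector of log-weights (or accuracies).
#' @param precision positive inverse-temperature multiplying \code{v}.
#' @return probability vector proportional to \code{exp(precision * v)}.
#' @export
softmax <- function(v, precision = 1) {
  if (!all(is.finite(v))) stop("non-finite input to softmax")
  x <- precision * v
  x <- exp(x - max(x))
  x / sum(x)
}

#' Information distance between grouped categorical columns
#'
#' Each column of \code{O} stacks \code{G} categorical marginals.  The
#' distance is the chord distance between the columns on the unit
#' hypersphere after Euclidean normalisation:
#' \code{2 * sqrt(2 * G * (1 - cos))}, where \code{cos} is the inner product
#' of the normalised columns.
#'
#' @param O numeric matrix of stacked marginals (columns are outcomes).
#' @param G number of marginals stacked in each column.
#' @return symmetric distance matrix with zero diagonal.
#' @export
info_distance <- function(O, G = 1L) {
  nrm <- sqrt(colSums(O^2))
  if (any(nrm == 0)) stop("zero column cannot be normalised")
  eta <- sweep(O, 2L, nrm, "/")
  C <- pmin(pmax(crossprod(eta), -1), 1)
  D <- 2 * sqrt(pmax(2 * G * (1 - C), 0))
  diag(D) <- 0
  D
}

#' Group identical (or informationally close) columns
#'
#' In \code{precise} mode, columns are grouped when they share the same
#' support pattern (the same set of non-zero entries); this is the lossless
#' rule apt for one-hot observations.  Otherwise columns are grouped when
#' their \code{\link{info_distance}} to a group representative is below one
#' natural unit.
#'
#' @param O numeric matrix whose columns are concatenated outcome vectors.
#' @param precise logical; use the support-pattern rule.
#' @param G group size passed to \code{\link{info_distance}} in soft mode.
#' @return list with \code{k} (for each column, the index of its group's
#'   representative column), \code{groups} (the distinct representative
#'   indices, in order of first appearance) and \code{R}, the T x K 0/1
#'   assignment matrix with exactly one 1 per row.
#' @export
unique_columns <- function(O, precise = TRUE, G = 1L) {
  Tn <- ncol(O)
  if (Tn == 0L) stop("empty input")
  if (precise) {
    keys <- apply(O > 0, 2L, paste, collapse = "")
    reps <- !duplicated(keys)
    first <- match(keys, keys[reps])          # group number per column
    groups <- which(reps)
    k <- groups[first]
  } else {
    D <- info_distance(O, G)
    groups <- integer(0)
    k <- integer(Tn)
    for (i in seq_len(Tn)) {
      hit <- groups[which(D[i, groups] < 1)[1L]]
      if (is.na(hit) || !length(hit)) {
        groups <- c(groups, i)
        k[i] <- i
      } else k[i] <- hit
    }
    first <- match(k, groups)
  }
  K <- length(groups)
  R <- matrix(0L, Tn, K)
  R[cbind(seq_len(Tn), first)] <- 1L
  list(k = k, groups = groups, R = R)
}

.plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information encoded by a Dirichlet count matrix
#'
#' Normalises the counts over \emph{all} entries to a joint distribution and
#' returns the sum of its marginal plug-in entropies minus the joint plug-in
#' entropy.  With \code{use_digamma = TRUE} the logs are replaced by
#' digamma-based expected logs under the Dirichlet.
#'
#' @param a non-negative count matrix with positive total.
#' @param use_digamma logical; use expected logs instead of plain logs.
#' @return mutual information in nats (non-negative for the plug-in form).
#' @export
dirichlet_mutual_info <- function(a, use_digamma = FALSE) {
  tot <- sum(a)
  if (tot <= 0) stop("all-zero count tensor")
  ab <- a / tot
  if (!use_digamma) {
    Hrow <- .plugin_entropy(rowSums(ab))
    Hcol <- .plugin_entropy(colSums(ab))
    Hjoint <- .plugin_entropy(as.vector(ab))
    return(Hrow + Hcol - Hjoint)
  }
  l <- function(x) digamma(pmax(x * tot, 1e-16)) - digamma(tot)
  Hrow <- -sum(rowSums(ab) * l(rowSums(ab)))
  Hcol <- -sum(colSums(ab) * l(colSums(ab)))
  Hjoint <- -sum(ab * l(ab))
  Hrow + Hcol - Hjoint
}
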