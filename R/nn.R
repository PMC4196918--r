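#' Nearest-neighbor differential entropy
#'
#' Kozachenko-Leonenko style estimate of the differential entropy of a
#' `d`-dimensional sample from the distances to each point's `k`-th nearest
#' neighbor. With the maximum norm the unit-ball volume term vanishes.
#'
#' @param X numeric matrix (rows = points) or vector.
#' @param k neighbor count.
#' @param norm `"max"` or `"euclidean"`.
#' @return entropy in nats.
#' @examples
#' set.seed(1)
#' nn_entropy(rnorm(2000), k = 10)  # close to 0.5 * log(2 * pi * exp(1))
#' @export
nn_entropy <- function(X, k = 10L, norm = c("max", "euclidean")) {
  norm <- match.arg(norm)
  X <- as.matrix(X)
  cpp_nn_entropy(X, as.integer(k), norm == "euclidean")
}

#' Nearest-neighbor conditional mutual information
#'
#' `I(y ; C | S)` estimated with a `k`-nearest-neighbor search in the joint
#' `(y, C, S)` space and strict range counts in the projected subspaces,
#' combined through digamma functions. The shared radius compensates the bias
#' of the individual entropy terms across spaces of different dimension. With
#' empty `S` this reduces to the plain nearest-neighbor mutual information.
#' Estimates can be slightly negative; raw values are returned.
#'
#' @param y target vector.
#' @param C candidate/driver columns (vector or matrix).
#' @param S conditioning columns (matrix, possibly `NULL`/0 columns).
#' @param k neighbor count.
#' @param norm `"max"` or `"euclidean"`.
#' @return conditional mutual information in nats.
#' @export
nn_cmi <- function(y, C, S = NULL, k = 10L, norm = c("max", "euclidean")) {
  norm <- match.arg(norm)
  y <- as.numeric(y)
  C <- as.matrix(C)
  if (is.null(S)) S <- matrix(0, length(y), 0L)
  S <- as.matrix(S)
  cpp_nn_cmi(y, C, S, as.integer(k), norm == "euclidean")
}

#' Nearest-neighbor transfer entropy
#'
#' Transfer entropy as the conditional mutual information between the target
#' present and the driver's selected past, given the remaining selected past:
#' the four entropy terms share the neighbor radius found in the
#' highest-dimensional space (neighbor search there, range searches in the
#' projections).
#'
#' @param y target vector.
#' @param X_src the driver's embedding columns.
#' @param X_rest the remaining embedding columns (target's own past and
#'   conditioning series).
#' @inheritParams nn_cmi
#' @return TE in nats.
#' @export
nn_te <- function(y, X_src, X_rest = NULL, k = 10L, norm = c("max", "euclidean")) {
  nn_cmi(y, X_src, X_rest, k = k, norm = norm)
}

#' @export
est_columns.mvte_est_nn <- function(est, x) as.numeric(x)

#' @export
est_ce.mvte_est_nn <- function(est, y, X) {
  # joint-minus-marginal entropies; used only where a lone CE is requested.
  if (is.null(X)) X <- matrix(0, length(y), 0L)
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(nn_entropy(y, est$k, est$norm))
  nn_entropy(cbind(y, X), est$k, est$norm) - nn_entropy(X, est$k, est$norm)
}

#' @export
est_te.mvte_est_nn <- function(est, y, X_src, X_rest) {
  if (is.null(X_rest)) X_rest <- matrix(0, length(y), 0L)
  nn_cmi(y, X_src, X_rest, k = est$k, norm = est$norm)
}

#' @export
est_score.mvte_est_nn <- function(est, y, cand, S) {
  nn_cmi(y, cand, S, k = est$k, norm = est$norm)
}

#' @export
est_null_kind.mvte_est_nn <- function(est) "shuffle_pair"
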