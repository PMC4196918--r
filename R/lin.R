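#' Least-squares fit without intercept
#'
#' Regression backbone of the linear (Gaussian) estimator. The design carries
#' no intercept because all series are standardized to zero mean before
#' estimation. Rank-deficient designs fall back to the minimum-norm
#' (pseudo-inverse) solution with a warning, flagged in the result.
#'
#' @param y response vector.
#' @param X design matrix (may have zero columns: the null model, for which
#'   the residuals are `y` itself).
#' @return list with `coefficients`, `residuals`, `rss`, `sigma2`
#'   (`rss/n`, the maximum-likelihood residual variance) and `rank_deficient`.
#' @export
lin_fit <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("rows(X) must equal length(y)")
  p <- ncol(X)
  rank_def <- FALSE
  if (p == 0L) {
    res <- y
    coefs <- numeric(0)
  } else {
    if (n <= p) stop("need more observations than regressors")
    qx <- qr(X)
    if (qx$rank < p) {
      warning("rank-deficient design; minimum-norm solution used")
      rank_def <- TRUE
    }
    coefs <- qr.coef(qx, y)
    coefs[is.na(coefs)] <- 0
    res <- y - X %*% coefs
  }
  rss <- sum(res^2)
  list(coefficients = as.numeric(coefs), residuals = as.numeric(res),
       rss = rss, sigma2 = rss / n, rank_deficient = rank_def)
}

#' Linear transfer entropy from nested regressions
#'
#' Transfer entropy of the Gaussian linear estimator:
#' `TE = 1/2 * log(sigma2_restricted / sigma2_unrestricted)` in nats, the
#' log-ratio of residual variances of the restricted and unrestricted
#' least-squares regressions of the target present on its reconstructed past.
#' For nested designs the value is non-negative up to numerical noise.
#'
#' @param y target vector.
#' @param X_full unrestricted design (restricted columns plus the driver's).
#' @param X_restricted design without the driver's columns.
#' @return TE in nats (`Inf` with a warning if the unrestricted residual
#'   variance is exactly zero).
#' @export
lin_te <- function(y, X_full, X_restricted) {
  fu <- lin_fit(y, X_full)
  fr <- lin_fit(y, X_restricted)
  if (fu$rss == 0) {
    if (fr$rss == 0) return(0)
    warning("zero unrestricted residual variance; TE is infinite")
    return(Inf)
  }
  0.5 * log(fr$rss / fu$rss)
}

#' @export
est_columns.mvte_est_lin <- function(est, x) as.numeric(x)

#' @export
est_ce.mvte_est_lin <- function(est, y, X) {
  # 1/2 log(sigma2); the Gaussian constant (2*pi*e)/2 cancels in differences
  0.5 * log(lin_fit(y, X)$sigma2)
}

#' @export
est_score.mvte_est_lin <- function(est, y, cand, S) {
  -est_ce(est, y, cbind(S, cand))
}

#' @export
est_null_kind.mvte_est_lin <- function(est) "time_shift"

#' Select the regression order by the Bayesian information criterion
#'
#' Fits the full multivariate autoregression of all series on lags `1..p` of
#' all series by least squares, for each `p` up to `max_order`, on the common
#' sample implied by `max_order`, and returns the order minimizing
#' `n * log(det(Sigma_p)) + log(n) * p * M^2` where `Sigma_p` is the
#' maximum-likelihood residual covariance.
#'
#' @param ts an `mvte_ts`.
#' @param max_order largest order considered.
#' @return integer order in `1..max_order`.
#' @export
select_order_bic <- function(ts, max_order) {
  stopifnot(inherits(ts, "mvte_ts"), max_order >= 1)
  M <- n_series(ts); N <- n_samples(ts)
  if (max_order * M >= N / 2) stop("max_order too large for the series length")
  if (max_order == 1L) return(1L)
  tt <- (max_order + 1L):N
  n <- length(tt)
  Y <- t(ts$data[, tt, drop = FALSE])
  lag_cols <- lapply(seq_len(max_order), function(l) t(ts$data[, tt - l, drop = FALSE]))
  bic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    X <- do.call(cbind, lag_cols[seq_len(p)])
    qx <- qr(X)
    E <- Y - X %*% qr.coef(qx, Y)
    S <- crossprod(E) / n
    ld <- determinant(S, logarithm = TRUE)$modulus
    bic[p] <- n * as.numeric(ld) + log(n) * (p * M * M)
  }
  which.min(bic)
}
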