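#' Circularly time-shift a series
#'
#' Null replicates for surrogate testing: the series is rotated by a lag
#' drawn uniformly from `[min_shift, N - min_shift]`, large enough to destroy
#' cross-dependence while preserving the multiset of values and the
#' autocorrelation structure.
#'
#' @param x numeric (or integer symbol) vector.
#' @param min_shift smallest admissible shift (kept away from both ends to
#'   avoid residual autocorrelation effects).
#' @param shift optional forced shift (for reproducible fixtures); otherwise
#'   drawn from the session RNG.
#' @return the rotated vector.
#' @export
time_shift <- function(x, min_shift = 20L, shift = NULL) {
  N <- length(x)
  if (min_shift < 1L || min_shift >= N - min_shift)
    stop("series too short for min_shift = ", min_shift)
  s <- if (is.null(shift)) sample(min_shift:(N - min_shift), 1L) else as.integer(shift)
  x[c((s + 1L):N, 1L:s)]
}

# Nearest-rank acceptance rule: with B null values and an adjusted level a,
# the observed statistic is accepted when it strictly exceeds the
# ceiling((1-a)*B)-th order statistic, i.e. when at most B - ceiling((1-a)*B)
# nulls reach it.
null_allowance <- function(B, level) B - as.integer(ceiling((1 - level) * B))

#' Null scores for a greedy candidate
#'
#' Builds the estimator-specific null distribution for the candidate
#' significance test of the non-uniform embedding: the linear and binning
#' estimators time-shift the winning candidate column; the nearest-neighbor
#' estimator shuffles the candidate and the target independently. Each
#' replicate recomputes the same selection statistic used to pick the winner,
#' with the previously selected columns untouched.
#'
#' @param est an [estimator_config()].
#' @param y target column (estimator representation).
#' @param winner_col the winning candidate column.
#' @param selected_cols matrix of already-selected columns (0 columns allowed).
#' @param n_null number of replicates.
#' @param min_shift minimum time shift (time-shift nulls only).
#' @return numeric vector of `n_null` null scores.
#' @export
candidate_null <- function(est, y, winner_col, selected_cols = NULL,
                           n_null = 100L, min_shift = 20L) {
  if (is.null(selected_cols)) selected_cols <- matrix(0, length(y), 0L)
  selected_cols <- as.matrix(selected_cols)
  kind <- est_null_kind(est)
  if (kind == "time_shift") {
    vapply(seq_len(n_null), function(b) {
      est_score(est, y, time_shift(winner_col, min_shift), selected_cols)
    }, numeric(1))
  } else {
    as.numeric(cpp_nn_cmi_null(as.numeric(y), as.matrix(as.numeric(winner_col)),
                               selected_cols, est$k, est$norm == "euclidean",
                               as.integer(n_null), Inf, as.integer(n_null)))
  }
}

# internal: candidate test with Bonferroni correction for the m candidates
# screened at this step and early stopping once rejection is certain.
# Returns list(accept, n_null_used, exceed, threshold_level).
candidate_test <- function(est, y, winner_col, selected_cols, stat,
                           m, alpha, n_null, min_shift, mult_adjust = TRUE) {
  level <- if (mult_adjust) alpha / m else alpha
  B <- if (mult_adjust) max(n_null, as.integer(ceiling(m / alpha)) - 1L) else n_null
  allow <- null_allowance(B, level)
  kind <- est_null_kind(est)
  if (kind == "shuffle_pair") {
    nulls <- as.numeric(cpp_nn_cmi_null(as.numeric(y),
                                        as.matrix(as.numeric(winner_col)),
                                        as.matrix(selected_cols), est$k,
                                        est$norm == "euclidean",
                                        as.integer(B), stat,
                                        as.integer(allow)))
    exceed <- sum(nulls >= stat)
  } else {
    exceed <- 0L
    b <- 0L
    while (b < B && exceed <= allow) {
      v <- est_score(est, y, time_shift(winner_col, min_shift), selected_cols)
      if (v >= stat) exceed <- exceed + 1L
      b <- b + 1L
    }
  }
  list(accept = exceed <= allow, exceed = exceed, level = level, n_null = B)
}

#' Time-shift surrogate test for uniformly embedded transfer entropy
#'
#' Significance of a transfer-entropy value under uniform embedding for the
#' model-free estimators: the driver's series is circularly shifted by a
#' random lag, the embedding columns are rebuilt, and TE is recomputed; this
#' is repeated `n_null` times. The original TE is significant when it
#' strictly exceeds the `100*(1-alpha)` nearest-rank percentile of the null
#' distribution.
#'
#' @param ts a normalized `mvte_ts`.
#' @param target,source series indices.
#' @param est a `"bin"` or `"nn"` [estimator_config()].
#' @param d embedding dimension per series.
#' @param m embedding delay.
#' @param conditioning indices of conditioning series (defaults to all
#'   remaining series).
#' @param alpha significance level.
#' @param n_null number of surrogates.
#' @param min_shift minimum shift.
#' @param instantaneous series allowed to contribute their lag-0 sample.
#' @return An object of class `mvte_verdict`: `statistic` (the TE),
#'   `threshold`, `p_like`, `significant`, `method`, `null` (the null TEs).
#' @export
ue_surrogate_test <- function(ts, target, source, est, d, m = 1L,
                              conditioning = NULL, alpha = 0.05,
                              n_null = 100L, min_shift = 20L,
                              instantaneous = integer(0)) {
  if (!est$kind %in% c("bin", "nn"))
    stop("surrogate UE testing applies to the bin and nn estimators; ",
         "the linear UE method uses f_test_lin_ue()")
  eng <- ue_engine(ts, target, est, d = d, m = m, conditioning = conditioning,
                   instantaneous = instantaneous)
  stat <- eng$te(source)
  nulls <- vapply(seq_len(n_null), function(b) eng$te_shifted(source, min_shift),
                  numeric(1))
  thr <- sort(nulls)[as.integer(ceiling((1 - alpha) * n_null))]
  verdict(stat, thr, nulls, stat > thr,
          sprintf("%s UE time-shift surrogates", toupper(est$kind)))
}

verdict <- function(statistic, threshold, null, significant, method) {
  structure(list(statistic = statistic, threshold = threshold,
                 p_like = (1 + sum(null >= statistic)) / (1 + length(null)),
                 significant = significant, method = method, null = null),
            class = "mvte_verdict")
}

#' @export
print.mvte_verdict <- function(x, ...) {
  cat(sprintf("<mvte_verdict> %s\n  statistic %.5g, threshold %.5g, p ~ %.4f -> %s\n",
              x$method, x$statistic, x$threshold, x$p_like,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Parametric F-test for the linear uniform-embedding transfer entropy
#'
#' Tests the null hypothesis that the driver's regression coefficients in the
#' unrestricted model are all zero:
#' `F = ((rss_r - rss_u)/p_source) / (rss_u/(n_obs - q_full))`, compared to
#' the Fisher quantile with `(p_source, n_obs - q_full)` degrees of freedom.
#'
#' @param rss_r,rss_u residual sums of squares of the restricted and
#'   unrestricted regressions (`rss_r >= rss_u` for nested designs).
#' @param p_source number of driver regressors removed in the restriction.
#' @param n_obs number of observations.
#' @param q_full total number of regressors of the unrestricted model.
#' @param alpha significance level.
#' @return An `mvte_verdict` with the F statistic.
#' @export
f_test_lin_ue <- function(rss_r, rss_u, p_source, n_obs, q_full, alpha = 0.05) {
  if (rss_u <= 0) stop("rss_u must be positive")
  if (n_obs <= q_full) stop("n_obs must exceed q_full")
  if (rss_r < rss_u * (1 - 1e-10)) stop("non-nested models: rss_r < rss_u")
  df2 <- n_obs - q_full
  f <- ((rss_r - rss_u) / p_source) / (rss_u / df2)
  thr <- stats::qf(1 - alpha, p_source, df2)
  structure(list(statistic = f, threshold = thr,
                 p_like = stats::pf(f, p_source, df2, lower.tail = FALSE),
                 significant = f > thr,
                 method = sprintf("LIN UE F-test (%d, %d df)", p_source, df2),
                 null = NULL),
            class = "mvte_verdict")
}
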