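#' Uniform embedding of the past
#'
#' Fixed a-priori reconstruction: every involved series contributes the lags
#' `m, 2m, ..., d*m`, enumerated target first, then the source, then the
#' conditioning series by index. Optionally, drivers flagged for
#' instantaneous effects also contribute their lag-0 sample.
#'
#' @param target,source series indices.
#' @param conditioning remaining series indices.
#' @param d embedding dimension per series.
#' @param m embedding delay.
#' @param instantaneous series indices whose lag-0 term is included (never
#'   the target).
#' @return An `mvte_embedding` with `d * (number of series)` terms (plus any
#'   lag-0 terms) and attribute `anchor_lag = d * m`.
#' @examples
#' uniform_embedding(target = 1, source = 2, conditioning = 3:5, d = 5)
#' @export
uniform_embedding <- function(target, source, conditioning = integer(0),
                              d, m = 1L, instantaneous = integer(0)) {
  stopifnot(d >= 1, m >= 1)
  if (target %in% instantaneous) stop("target cannot have instantaneous terms")
  series <- c(target, source, sort(setdiff(conditioning, c(target, source))))
  lags <- seq_len(d) * m
  terms <- do.call(rbind, lapply(series, function(s) {
    l <- lags
    if (s %in% instantaneous) l <- c(l, 0L)
    data.frame(series = s, lag = l)
  }))
  emb <- embedding(target, terms, source = source,
                   conditioning = setdiff(series, c(target, source)))
  attr(emb, "anchor_lag") <- as.integer(d * m)
  emb
}

#' Parameters of the non-uniform embedding selection
#'
#' @param alpha per-step candidate significance level.
#' @param n_null minimum size of the candidate null distribution.
#' @param min_shift minimum lag of time-shift nulls.
#' @param mult_adjust if `TRUE`, apply a Bonferroni correction for the
#'   number of candidates screened at each step (the null sample is enlarged
#'   so the corrected percentile is resolvable). The default `FALSE` tests
#'   the winner at the raw `alpha` level against its own null. The raw test
#'   is calibrated per candidate but not family-wise: for targets whose
#'   candidates are serially uncorrelated (e.g. white noise) the greedy
#'   maximization makes it accept junk terms far more often than `alpha`;
#'   with autocorrelated data the time-shift nulls inherit the inflated
#'   variance of dependent-sample statistics, which in practice restores
#'   much of the selectivity. Enable the correction when the empty-embedding
#'   guarantee for structureless targets matters more than per-link
#'   sensitivity; see the methods vignette for measurements of both modes.
#' @return list of class `mvte_nue_params`.
#' @export
nue_params <- function(alpha = 0.05, n_null = 100L, min_shift = 20L,
                       mult_adjust = FALSE) {
  stopifnot(alpha > 0, alpha < 1, n_null >= 20L, min_shift >= 1L)
  structure(list(alpha = alpha, n_null = as.integer(n_null),
                 min_shift = as.integer(min_shift),
                 mult_adjust = isTRUE(mult_adjust)),
            class = "mvte_nue_params")
}

# estimator-ready lagged columns for a candidate set; all columns share the
# anchor implied by the candidate set so every entropy term within a run is
# evaluated on identical rows.
candidate_columns <- function(ts, cs, est) {
  if (!ts$normalized) ts <- normalize_ts(ts)
  N <- n_samples(ts)
  anchor <- max(cs$lag)
  reps <- lapply(seq_len(n_series(ts)), function(s) est_columns(est, ts$data[s, ]))
  tt <- (anchor + 1L):N
  X <- matrix(0, length(tt), nrow(cs))
  for (j in seq_len(nrow(cs))) X[, j] <- reps[[cs$series[j]]][tt - cs$lag[j]]
  list(y = reps[[attr(cs, "target")]][tt], X = X, anchor = anchor, reps = reps,
       tt = tt)
}

#' Greedy non-uniform embedding selection
#'
#' Iteratively builds the embedding of the past for one target: at each step
#' every remaining candidate is scored by the information it adds about the
#' target given the terms already selected (conditional-entropy decrease for
#' the linear and binning estimators, conditional mutual information for
#' nearest neighbors); the best candidate is kept only if its contribution
#' passes a randomization test, otherwise the procedure stops. A target
#' carrying no detectable structure (e.g. white noise) yields an empty
#' embedding.
#'
#' @param ts an `mvte_ts` (normalized internally if needed).
#' @param cs a [build_candidate_set()] for the target.
#' @param est an [estimator_config()].
#' @param nue a [nue_params()] list.
#' @return list with `embedding` (an `mvte_embedding`, terms in selection
#'   order, attribute `anchor_lag`) and `trace` (one row per step: candidates
#'   tested, winner, score, contribution, null exceedances, null size,
#'   accepted flag).
#' @export
nue_select <- function(ts, cs, est, nue = nue_params()) {
  stopifnot(inherits(cs, "mvte_candidates"), inherits(est, "mvte_estimator"))
  target <- attr(cs, "target")
  cc <- candidate_columns(ts, cs, est)
  y <- cc$y
  pool <- seq_len(nrow(cs))
  sel <- integer(0)
  ce_prev <- if (est$kind == "nn") NA_real_ else est_ce(est, y, NULL)
  trace <- list()
  n_evals <- 0L
  repeat {
    if (!length(pool)) break
    S <- cc$X[, sel, drop = FALSE]
    scores <- vapply(pool, function(j) est_score(est, y, cc$X[, j], S), numeric(1))
    n_evals <- n_evals + length(pool)
    w <- which.max(scores)  # ties -> lowest enumeration index
    j <- pool[w]
    contribution <- if (est$kind == "nn") scores[w] else scores[w] + ce_prev
    tst <- candidate_test(est, y, cc$X[, j], S, scores[w], m = length(pool),
                          alpha = nue$alpha, n_null = nue$n_null,
                          min_shift = nue$min_shift,
                          mult_adjust = nue$mult_adjust)
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, tested = length(pool),
      series = cs$series[j], lag = cs$lag[j], score = scores[w],
      contribution = contribution, null_exceed = tst$exceed,
      n_null = tst$n_null, accepted = tst$accept)
    if (!tst$accept) break
    sel <- c(sel, j)
    pool <- pool[-w]
    if (est$kind != "nn") ce_prev <- -max(scores)
  }
  emb <- embedding(target, cs[sel, c("series", "lag"), drop = FALSE])
  attr(emb, "anchor_lag") <- cc$anchor
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), tested = integer(0), series = integer(0),
               lag = integer(0), score = numeric(0), contribution = numeric(0),
               null_exceed = integer(0), n_null = integer(0),
               accepted = logical(0))
  attr(trace, "n_score_evals") <- n_evals
  list(embedding = emb, trace = trace)
}

#' Transfer entropy from a chosen embedding
#'
#' Evaluates `TE = CE1 - CE2` for a driver: `CE2` conditions the target's
#' present on all embedding terms, `CE1` on the embedding without the
#' driver's terms. When the embedding contains no term of the driver the TE
#' is exactly zero (and, for a non-uniformly selected embedding, counted as
#' non-significant).
#'
#' @param emb an `mvte_embedding`.
#' @param est an [estimator_config()].
#' @param ts the `mvte_ts` the embedding refers to.
#' @param source the driver series.
#' @param anchor_lag row-alignment anchor; defaults to the embedding's
#'   `anchor_lag` attribute (or its maximum lag).
#' @return TE in nats.
#' @export
te_from_embedding <- function(emb, est, ts, source, anchor_lag = NULL) {
  if (!ts$normalized) ts <- normalize_ts(ts)
  src <- emb$terms$series == source
  if (!any(src)) return(0)
  if (is.null(anchor_lag)) {
    anchor_lag <- attr(emb, "anchor_lag")
    if (is.null(anchor_lag)) anchor_lag <- max(emb$terms$lag)
  }
  N <- n_samples(ts)
  tt <- (anchor_lag + 1L):N
  reps <- lapply(seq_len(n_series(ts)), function(s) est_columns(est, ts$data[s, ]))
  X <- matrix(0, length(tt), nrow(emb$terms))
  for (j in seq_len(nrow(emb$terms)))
    X[, j] <- reps[[emb$terms$series[j]]][tt - emb$terms$lag[j]]
  y <- reps[[emb$target]][tt]
  est_te(est, y, X[, src, drop = FALSE], X[, !src, drop = FALSE])
}

# Shared uniform-embedding computation for one target: estimator columns for
# all series at lags m..d*m (plus instantaneous terms), with TE and
# shifted-source TE evaluators. CE1-type terms are cached per driver since
# they do not involve the driver's columns.
ue_engine <- function(ts, target, est, d, m = 1L, conditioning = NULL,
                      instantaneous = integer(0)) {
  if (!ts$normalized) ts <- normalize_ts(ts)
  M <- n_series(ts)
  if (is.null(conditioning)) conditioning <- setdiff(seq_len(M), target)
  series <- c(target, sort(setdiff(conditioning, target)))
  N <- n_samples(ts)
  anchor <- as.integer(d * m)
  if (anchor >= N) stop("d * m must be smaller than the series length")
  tt <- (anchor + 1L):N
  reps <- lapply(seq_len(M), function(s) est_columns(est, ts$data[s, ]))
  lag_of <- function(s) {
    l <- seq_len(d) * m
    if (s %in% instantaneous && s != target) l <- c(l, 0L)
    l
  }
  terms <- do.call(rbind, lapply(series, function(s)
    data.frame(series = s, lag = lag_of(s))))
  cols <- function(rep_s, lags) {
    out <- matrix(0, length(tt), length(lags))
    for (j in seq_along(lags)) out[, j] <- rep_s[tt - lags[j]]
    out
  }
  X <- matrix(0, length(tt), nrow(terms))
  for (j in seq_len(nrow(terms)))
    X[, j] <- reps[[terms$series[j]]][tt - terms$lag[j]]
  y <- reps[[target]][tt]
  ce1_cache <- new.env(parent = emptyenv())
  list(
    terms = terms, y = y, X = X, anchor = anchor, n_obs = length(tt),
    te = function(source) {
      src <- terms$series == source
      if (!any(src)) stop("source not part of the embedding scope")
      est_te(est, y, X[, src, drop = FALSE], X[, !src, drop = FALSE])
    },
    te_shifted = function(source, min_shift) {
      src <- terms$series == source
      key <- as.character(source)
      ce1 <- ce1_cache[[key]]
      Xr <- X[, !src, drop = FALSE]
      if (est$kind == "nn") {
        Xs <- cols(time_shift(reps[[source]], min_shift), terms$lag[src])
        return(est_te(est, y, Xs, Xr))
      }
      if (is.null(ce1)) {
        ce1 <- est_ce(est, y, Xr)
        ce1_cache[[key]] <- ce1
      }
      Xs <- cols(time_shift(reps[[source]], min_shift), terms$lag[src])
      ce1 - est_ce(est, y, cbind(Xs, Xr))
    })
}
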