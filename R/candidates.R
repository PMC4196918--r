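#' Enumerate the candidate (series, lag) terms for one target
#'
#' Builds the ordered candidate set from which the embedding of the past is
#' drawn: for every series, lags `1..max_lag`; series flagged for
#' instantaneous effects additionally contribute their lag-0 sample, appended
#' after the lagged terms of that series. The target itself never appears at
#' lag 0. Enumeration is series-major with lags ascending and defines the
#' tie-break order used throughout the greedy selection.
#'
#' @param M number of series.
#' @param max_lag maximum lag, either a single integer or one per series.
#' @param instantaneous integer indices of series whose lag-0 term is a
#'   permitted candidate (measurement conventions allowing same-sample
#'   influence); must not contain `target`.
#' @param target index of the target series.
#' @return A data.frame of class `mvte_candidates` with columns `series`,
#'   `lag`, and attributes `max_lag`, `instantaneous`, `target`, `M`.
#' @examples
#' build_candidate_set(M = 3, max_lag = 2, instantaneous = 1, target = 2)
#' @export
build_candidate_set <- function(M, max_lag, instantaneous = integer(0), target) {
  stopifnot(M >= 1, target >= 1, target <= M)
  max_lag <- rep_len(as.integer(max_lag), M)
  if (any(max_lag < 1)) stop("max_lag must be >= 1 for every series")
  instantaneous <- as.integer(instantaneous)
  if (target %in% instantaneous)
    stop("the target series cannot be in the instantaneous-effects set")
  if (length(instantaneous) && any(instantaneous < 1 | instantaneous > M))
    stop("instantaneous indices out of range")
  rows <- do.call(rbind, lapply(seq_len(M), function(s) {
    lags <- seq_len(max_lag[s])
    if (s %in% instantaneous) lags <- c(lags, 0L)  # lag-0 appended per series
    cbind(series = s, lag = lags)
  }))
  cs <- as.data.frame(rows)
  attr(cs, "max_lag") <- max_lag
  attr(cs, "instantaneous") <- instantaneous
  attr(cs, "target") <- as.integer(target)
  attr(cs, "M") <- as.integer(M)
  class(cs) <- c("mvte_candidates", "data.frame")
  cs
}

#' An embedding: the selected past terms for one target
#'
#' @param target target series index.
#' @param terms data.frame with columns `series`, `lag` (possibly 0 rows).
#' @param source the tested driver series index (may be `NA` when the
#'   embedding is driver-agnostic, as after non-uniform selection).
#' @param conditioning indices of the remaining conditioning series.
#' @return An object of class `mvte_embedding`.
#' @export
embedding <- function(target, terms, source = NA_integer_,
                      conditioning = integer(0)) {
  terms <- as.data.frame(terms)
  if (nrow(terms) == 0L) terms <- data.frame(series = integer(0), lag = integer(0))
  stopifnot(all(c("series", "lag") %in% names(terms)))
  structure(list(target = as.integer(target), terms = terms,
                 source = as.integer(source),
                 conditioning = as.integer(conditioning)),
            class = "mvte_embedding")
}

#' @export
print.mvte_embedding <- function(x, ...) {
  cat(sprintf("<mvte_embedding> target %d, %d term(s)\n", x$target, nrow(x$terms)))
  if (nrow(x$terms))
    cat(paste0("  (", x$terms$series, ", lag ", x$terms$lag, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Restrict an embedding by dropping all terms of one series
#'
#' The restricted view used for the first conditional-entropy term: the
#' selected past without any component of the tested driver.
#'
#' @param emb an `mvte_embedding`.
#' @param source series whose terms are removed.
#' @export
restrict_embedding <- function(emb, source) {
  keep <- emb$terms$series != source
  embedding(emb$target, emb$terms[keep, , drop = FALSE], source = source,
            conditioning = emb$conditioning)
}

#' Align the target with its lagged design columns
#'
#' Builds the observation table shared by all entropy terms of one transfer
#' entropy computation: `y[i]` is the target at time `t0 + i` and column `j`
#' of `X` holds the `j`-th term's series at time `t0 + i - lag_j`. The anchor
#' (the largest lag of the governing candidate set) fixes `t0` so every
#' entropy term within a run is evaluated on the same rows, regardless of
#' which subset of terms it uses.
#'
#' @param ts an `mvte_ts`.
#' @param terms data.frame with columns `series`, `lag`.
#' @param target target series index.
#' @param anchor_lag the maximum lag of the governing candidate set; defaults
#'   to the maximum lag in `terms` (0 if none).
#' @return list with `y` (length `N - anchor_lag`), `X` (matrix with one
#'   column per term), `t0`.
#' @export
extract_observations <- function(ts, terms, target, anchor_lag = NULL) {
  stopifnot(inherits(ts, "mvte_ts"))
  terms <- as.data.frame(terms)
  N <- n_samples(ts)
  if (is.null(anchor_lag))
    anchor_lag <- if (nrow(terms)) max(terms$lag) else 0L
  anchor_lag <- as.integer(anchor_lag)
  if (nrow(terms) && anchor_lag < max(terms$lag))
    stop("anchor_lag smaller than the largest term lag")
  if (anchor_lag >= N) stop("anchor lag leaves no usable observations")
  tt <- (anchor_lag + 1L):N
  y <- ts$data[target, tt]
  X <- matrix(0, length(tt), nrow(terms))
  if (nrow(terms))
    for (j in seq_len(nrow(terms)))
      X[, j] <- ts$data[terms$series[j], tt - terms$lag[j]]
  list(y = y, X = X, t0 = anchor_lag)
}
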