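#' Methods available to the batch analyses
#'
#' A method pairs an estimator (`lin`, `bin`, `nn`) with an embedding
#' strategy (`ue`, `nue`).
#'
#' @return character vector of method names.
#' @export
mvte_methods <- function() {
  c("lin_ue", "bin_ue", "nn_ue", "lin_nue", "bin_nue", "nn_nue")
}

method_parts <- function(method) {
  method <- match.arg(method, mvte_methods())
  strsplit(method, "_", fixed = TRUE)[[1L]]
}

#' Conditional transfer-entropy analysis of one realization
#'
#' Computes the transfer entropy for every ordered pair `(i, j)` of series,
#' conditioned on all remaining series, with the significance machinery
#' appropriate to the method: parametric F-test for `lin_ue`, time-shift
#' surrogates of the source for `bin_ue`/`nn_ue`, and selection of at least
#' one source term for the non-uniform methods (where the greedy embedding is
#' built once per target and shared by all of its drivers).
#'
#' @param ts an `mvte_ts`.
#' @param method one of [mvte_methods()].
#' @param max_lag maximum candidate lag (uniform methods embed
#'   `d = max_lag` lags per series; the linear uniform method uses the BIC
#'   order unless `est$order` fixes it).
#' @param est an [estimator_config()]; defaults to the method's estimator
#'   with package defaults (`Q = 6`, `k = 10`, maximum norm).
#' @param alpha significance level.
#' @param n_null surrogate/null replicates.
#' @param min_shift minimum time shift for surrogates.
#' @param nue a [nue_params()] (non-uniform methods).
#' @param instantaneous series whose lag-0 sample may enter embeddings of
#'   other targets.
#' @param significance if `FALSE`, only the TE values are computed (the
#'   significance flags stay `NA`); useful for estimator-comparison studies
#'   where the surrogate loops dominate the cost. Non-uniform methods always
#'   carry their selection-based significance.
#' @return list of class `mvte_te_matrix`: `te` and `sig` are `M x M`
#'   matrices (`[i, j]` is the transfer `i -> j`; diagonal `NA`), plus
#'   `method` and per-target details.
#' @export
analyze_ts <- function(ts, method, max_lag = 5L, est = NULL, alpha = 0.05,
                       n_null = 100L, min_shift = 20L, nue = NULL,
                       instantaneous = integer(0), significance = TRUE) {
  parts <- method_parts(method)
  kind <- parts[1L]; emb <- parts[2L]
  if (is.null(est)) est <- estimator_config(kind)
  if (est$kind != kind) stop("estimator config does not match method")
  if (is.null(nue) && emb == "nue")
    nue <- nue_params(alpha = alpha, n_null = n_null, min_shift = min_shift)
  ts <- normalize_ts(ts)
  M <- n_series(ts)
  te <- matrix(NA_real_, M, M)
  sig <- matrix(NA, M, M)
  details <- vector("list", M)
  if (emb == "ue" && kind == "lin") {
    p <- if (is.null(est$order)) select_order_bic(ts, max_lag) else
      as.integer(est$order)
    for (j in seq_len(M)) {
      terms <- do.call(rbind, lapply(c(j, setdiff(seq_len(M), j)), function(s) {
        l <- seq_len(p)
        if (s %in% instantaneous && s != j) l <- c(l, 0L)
        data.frame(series = s, lag = l)
      }))
      obs <- extract_observations(ts, terms, j, anchor_lag = p)
      fu <- lin_fit(obs$y, obs$X)
      for (i in setdiff(seq_len(M), j)) {
        keep <- terms$series != i
        fr <- lin_fit(obs$y, obs$X[, keep, drop = FALSE])
        te[i, j] <- 0.5 * log(fr$rss / fu$rss)
        v <- f_test_lin_ue(fr$rss, fu$rss, sum(!keep), length(obs$y),
                           ncol(obs$X), alpha)
        sig[i, j] <- v$significant
      }
      details[[j]] <- list(order = p)
    }
  } else if (emb == "ue") {
    for (j in seq_len(M)) {
      eng <- ue_engine(ts, j, est, d = max_lag, m = 1L,
                       instantaneous = instantaneous)
      for (i in setdiff(seq_len(M), j)) {
        stat <- eng$te(i)
        te[i, j] <- stat
        if (significance) {
          nulls <- vapply(seq_len(n_null), function(b)
            eng$te_shifted(i, min_shift), numeric(1))
          thr <- sort(nulls)[as.integer(ceiling((1 - alpha) * n_null))]
          sig[i, j] <- stat > thr
        }
      }
    }
  } else {  # non-uniform embedding, one selection per target
    for (j in seq_len(M)) {
      cs <- build_candidate_set(M, max_lag,
                                instantaneous = setdiff(instantaneous, j),
                                target = j)
      selres <- nue_select(ts, cs, est, nue)
      for (i in setdiff(seq_len(M), j)) {
        te[i, j] <- te_from_embedding(selres$embedding, est, ts, i)
        sig[i, j] <- any(selres$embedding$terms$series == i)
      }
      details[[j]] <- selres
    }
  }
  structure(list(te = te, sig = sig, method = method, details = details),
            class = "mvte_te_matrix")
}

#' Run a method over a batch of realizations
#'
#' @param realizations a list of `mvte_ts` (e.g. from [simulate_batch()]).
#' @param method one of [mvte_methods()].
#' @param seed base seed for the analysis randomness (surrogates/nulls),
#'   mixed per realization so batches are reproducible and independent.
#' @param ... passed to [analyze_ts()].
#' @return list of class `mvte_batch` with `te` and `sig` arrays
#'   (`n_realizations x M x M`), `method`, and the batch's `truth` attribute
#'   if present.
#' @export
run_batch <- function(realizations, method, seed = 1L, ...) {
  stopifnot(length(realizations) >= 1L)
  M <- n_series(realizations[[1L]])
  if (!all(vapply(realizations, n_series, integer(1)) == M) ||
      length(unique(vapply(realizations, n_samples, integer(1)))) != 1L)
    stop("all realizations must have the same shape")
  R <- length(realizations)
  te <- array(NA_real_, c(R, M, M))
  sig <- array(NA, c(R, M, M))
  for (r in seq_len(R)) {
    set.seed(derive_seed(seed, 7919L + r))
    res <- analyze_ts(realizations[[r]], method, ...)
    te[r, , ] <- res$te
    sig[r, , ] <- res$sig
  }
  structure(list(te = te, sig = sig, method = method,
                 truth = attr(realizations, "truth")),
            class = "mvte_batch")
}

#' Count significant realizations for one directed pair
#'
#' @param batch an `mvte_batch`.
#' @param from,to series indices of the directed pair (off-diagonal).
#' @return integer count in `0..n_realizations`.
#' @export
count_significant <- function(batch, from, to) {
  if (from == to) stop("diagonal pairs are excluded")
  sum(batch$sig[, from, to])
}

#' Per-link summary of a batch
#'
#' @param batch an `mvte_batch`.
#' @param truth optional [ground_truth()]; defaults to the batch's own.
#' @return data.frame with one row per directed pair: `from`, `to`,
#'   `mean_te`, `n_sig`, `truth`.
#' @export
link_report <- function(batch, truth = NULL) {
  if (is.null(truth)) truth <- batch$truth
  M <- dim(batch$te)[2L]
  A <- if (!is.null(truth)) truth_adjacency(truth) else matrix(NA, M, M)
  pairs <- which(row(diag(M)) != col(diag(M)), arr.ind = TRUE)
  data.frame(
    from = pairs[, 1L], to = pairs[, 2L],
    mean_te = apply(pairs, 1L, function(p) mean(batch$te[, p[1L], p[2L]])),
    n_sig = apply(pairs, 1L, function(p) sum(batch$sig[, p[1L], p[2L]])),
    truth = A[pairs]
  )
}

#' Pooled sensitivity and specificity of a batch
#'
#' Detection counts are pooled over realizations and directed pairs, with all
#' coupled directions as positives and all uncoupled directions as negatives:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`.
#'
#' @inheritParams link_report
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
pooled_sens_spec <- function(batch, truth = NULL) {
  if (is.null(truth)) truth <- batch$truth
  if (is.null(truth)) stop("no ground truth available")
  A <- truth_adjacency(truth)
  M <- dim(batch$sig)[2L]
  R <- dim(batch$sig)[1L]
  off <- which(row(diag(M)) != col(diag(M)), arr.ind = TRUE)
  tp <- fp <- tn <- fn <- 0L
  for (q in seq_len(nrow(off))) {
    i <- off[q, 1L]; j <- off[q, 2L]
    s <- sum(batch$sig[, i, j])
    if (A[i, j]) { tp <- tp + s; fn <- fn + (R - s) }
    else { fp <- fp + s; tn <- tn + (R - s) }
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Sensitivity/specificity sweep over series length
#'
#' Repeats a batch analysis at increasing series lengths and reports the
#' pooled operating point at each, mirroring a receiver-operating sweep of
#' the detector as data become more plentiful.
#'
#' @param system benchmark name, as in [ground_truth()].
#' @param method one of [mvte_methods()].
#' @param lengths integer vector of series lengths.
#' @param n_realizations realizations per length.
#' @param seed base seed.
#' @param ... passed to [analyze_ts()] via [run_batch()].
#' @return data.frame with columns `length`, `sensitivity`, `specificity`.
#' @export
roc_sweep <- function(system, method, lengths = c(128L, 256L, 512L, 1024L),
                      n_realizations = 10L, seed = 1L, ...) {
  out <- lapply(seq_along(lengths), function(q) {
    reals <- simulate_batch(system, n = lengths[q],
                            n_realizations = n_realizations,
                            seed = derive_seed(seed, 1000L + q))
    b <- run_batch(reals, method, seed = derive_seed(seed, 2000L + q), ...)
    ss <- pooled_sens_spec(b)
    data.frame(length = lengths[q], sensitivity = ss$sensitivity,
               specificity = ss$specificity)
  })
  do.call(rbind, out)
}
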