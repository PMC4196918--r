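test_that("uniform embeddings enumerate the expected lags", {
  e <- uniform_embedding(target = 1, source = 2, d = 1, m = 1)
  expect_equal(paste(e$terms$series, e$terms$lag), c("1 1", "2 1"))

  e25 <- uniform_embedding(target = 1, source = 2, conditioning = 3:5, d = 5)
  expect_equal(nrow(e25$terms), 25L)
  expect_equal(attr(e25, "anchor_lag"), 5L)

  e2 <- uniform_embedding(target = 1, source = 2, d = 2, m = 3)
  expect_equal(sort(unique(e2$terms$lag)), c(3L, 6L))

  e0 <- uniform_embedding(target = 1, source = 2, d = 2, instantaneous = 2)
  expect_true(any(e0$terms$series == 2 & e0$terms$lag == 0))
})

test_that("greedy selection recovers a planted lag first", {
  first_hits <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 512
    x <- rnorm(n)
    y <- c(rnorm(2), x[1:(n - 2)]) + 0.3 * rnorm(n)
    ts <- ts_set(rbind(x, y))
    cs <- build_candidate_set(2, 5, target = 2)
    sel <- nue_select(ts, cs, estimator_config("lin"))
    tr <- sel$trace
    first_hits <- first_hits + (tr$series[1] == 1 && tr$lag[1] == 2)
  }
  expect_gte(first_hits, 9L)
})

test_that("selection traces are deterministic, duplicate-free and within the complexity bound", {
  set.seed(33)
  ts <- simulate_linear_ar5(256)
  cs <- build_candidate_set(5, 4, target = 4)
  est <- estimator_config("bin")
  set.seed(77); s1 <- nue_select(ts, cs, est)
  set.seed(77); s2 <- nue_select(ts, cs, est)
  expect_identical(s1$trace, s2$trace)

  terms <- s1$embedding$terms
  expect_equal(anyDuplicated(paste(terms$series, terms$lag)), 0L)

  numC <- nrow(cs)
  expect_lte(attr(s1$trace, "n_score_evals"), numC * (numC + 1) / 2)

  # running score is non-decreasing over accepted steps (CE minimization)
  acc <- s1$trace[s1$trace$accepted, ]
  if (nrow(acc) > 1) expect_true(all(diff(acc$score) >= -1e-12))
})

test_that("a single self-copy candidate is selected, then the loop stops by rejection", {
  set.seed(34)
  x <- as.numeric(arima.sim(list(ar = 0.7), 400))
  ts <- ts_set(rbind(x))
  cs <- build_candidate_set(1, 1, target = 1)
  set.seed(35)
  sel <- nue_select(ts, cs, estimator_config("lin"))
  expect_equal(nrow(sel$embedding$terms), 1L)
  expect_equal(sel$trace$accepted, TRUE)  # sole candidate accepted, pool empty
})

test_that("white-noise targets yield empty embeddings under family-wise correction", {
  empties <- 0L
  zero_te <- TRUE
  for (r in 1:12) {
    set.seed(200 + r)
    wn <- ts_set(matrix(rnorm(5 * 400), 5, 400))
    cs <- build_candidate_set(5, 5, target = 1)
    sel <- nue_select(wn, cs, estimator_config("bin"),
                      nue_params(mult_adjust = TRUE))
    if (nrow(sel$embedding$terms) == 0L) {
      empties <- empties + 1L
      zero_te <- zero_te &&
        identical(te_from_embedding(sel$embedding, estimator_config("bin"),
                                    wn, source = 2), 0)
    }
  }
  expect_gte(empties, 10L)
  expect_true(zero_te)
})

test_that("TE from an embedding honors the restricted/full split", {
  set.seed(36)
  ts <- normalize_ts(ts_set(matrix(rnorm(3 * 300), 3, 300)))
  emb <- embedding(1, data.frame(series = c(1, 2), lag = c(1, 1)))
  attr(emb, "anchor_lag") <- 2L
  # no terms of series 3: TE is exactly zero
  expect_identical(te_from_embedding(emb, estimator_config("bin"), ts, 3), 0)

  # BIN TE equals the four-entropy oracle
  est <- estimator_config("bin", Q = 3)
  te <- te_from_embedding(emb, est, ts, 2)
  q <- lapply(1:3, function(s) as.integer(quantize(ts$data[s, ], 3)))
  tt <- 3:300
  yq <- q[[1]][tt]; own <- q[[1]][tt - 1]; src <- q[[2]][tt - 1]
  oracle <- (oracle_bin_entropy(cbind(yq, own)) - oracle_bin_entropy(matrix(own))) -
    (oracle_bin_entropy(cbind(yq, src, own)) - oracle_bin_entropy(cbind(src, own)))
  expect_equal(te, oracle, tolerance = 1e-12)
  expect_gte(te, 0)
})

test_that("neighbor-based selection admits only positive conditional contributions", {
  set.seed(91)
  n <- 300
  x <- as.numeric(arima.sim(list(ar = 0.6), n))
  y <- 0.7 * c(0, x[-n]) + rnorm(n)
  ts <- ts_set(rbind(x, y))
  cs <- build_candidate_set(2, 3, target = 2)
  set.seed(92)
  sel <- nue_select(ts, cs, estimator_config("nn"))
  acc <- sel$trace[sel$trace$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$contribution > 0))
  expect_true(any(acc$series == 1 & acc$lag == 1))  # the planted driver term
  set.seed(92)
  sel2 <- nue_select(ts, cs, estimator_config("nn"))
  expect_identical(sel$trace, sel2$trace)
})
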