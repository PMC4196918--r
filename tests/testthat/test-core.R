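test_that("normalization gives zero mean, unit population variance, and is idempotent", {
  expect_equal(normalize_ts(ts_set(c(1, 3)))$data[1, ], c(-1, 1))

  set.seed(42)
  ts <- ts_set(matrix(rnorm(3 * 512, mean = 5, sd = 3), 3, 512))
  tn <- normalize_ts(ts)
  expect_true(all(abs(rowMeans(tn$data)) < 1e-10))
  expect_true(all(abs(rowMeans(tn$data^2) - 1) < 1e-8))

  tn2 <- normalize_ts(tn)
  expect_equal(tn2$data, tn$data, tolerance = 1e-12)
})

test_that("constant series cannot be normalized and the error names them", {
  ts <- ts_set(rbind(rnorm(50), rep(2, 50)), labels = c("ok", "flat"))
  expect_error(normalize_ts(ts), "flat")
})

test_that("candidate sets enumerate series-major with ascending lags", {
  cs <- build_candidate_set(M = 2, max_lag = 1, target = 2)
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$series, c(1L, 2L))
  expect_equal(cs$lag, c(1L, 1L))

  # five series at five lags span a 25-dimensional reconstructed past
  cs25 <- build_candidate_set(M = 5, max_lag = 5, target = 1)
  expect_equal(nrow(cs25), 25L)

  cs0 <- build_candidate_set(M = 3, max_lag = 2, instantaneous = 1, target = 2)
  expect_equal(nrow(cs0), 7L)
  expect_equal(
    paste(cs0$series, cs0$lag),
    c("1 1", "1 2", "1 0", "2 1", "2 2", "3 1", "3 2"))

  expect_error(build_candidate_set(3, 2, instantaneous = 2, target = 2),
               "instantaneous")
})

test_that("observation extraction aligns lagged columns with the target", {
  ts <- ts_set(matrix(c(1, 2, 3, 4), 1))
  obs <- extract_observations(ts, data.frame(series = 1, lag = 1), 1,
                              anchor_lag = 1)
  expect_equal(obs$y, c(2, 3, 4))
  expect_equal(obs$X[, 1], c(1, 2, 3))

  # empty term list: degenerate design with full-length target slice
  obs0 <- extract_observations(ts, data.frame(series = integer(0),
                                              lag = integer(0)), 1,
                               anchor_lag = 2)
  expect_equal(ncol(obs0$X), 0L)
  expect_equal(obs0$y, c(3, 4))

  # two series, mixed lags, checked element-wise against hand alignment
  ts2 <- ts_set(rbind(c(10, 20, 30, 40, 50), c(1, 2, 3, 4, 5)))
  obs2 <- extract_observations(ts2, data.frame(series = c(1, 2), lag = c(2, 1)),
                               target = 2, anchor_lag = 2)
  expect_equal(nrow(obs2$X), 3L)
  expect_equal(obs2$y, c(3, 4, 5))
  expect_equal(obs2$X[, 1], c(10, 20, 30))
  expect_equal(obs2$X[, 2], c(2, 3, 4))

  # a hypothetical lag-0 identity term reproduces the target slice
  obs3 <- extract_observations(ts2, data.frame(series = 2, lag = 0),
                               target = 2, anchor_lag = 2)
  expect_equal(obs3$X[, 1], obs3$y)

  expect_error(extract_observations(ts, data.frame(series = 1, lag = 3), 1,
                                    anchor_lag = 1), "anchor")
  expect_error(extract_observations(ts, data.frame(series = 1, lag = 1), 1,
                                    anchor_lag = 4), "observations")
})

test_that("column order of embedding terms does not change TE", {
  set.seed(7)
  ts <- normalize_ts(ts_set(matrix(rnorm(3 * 200), 3, 200)))
  terms <- data.frame(series = c(1, 1, 2, 3), lag = c(1, 2, 1, 2))
  for (kind in c("lin", "bin")) {
    est <- estimator_config(kind)
    emb1 <- embedding(2, terms)
    emb2 <- embedding(2, terms[c(3, 1, 4, 2), ])
    attr(emb1, "anchor_lag") <- attr(emb2, "anchor_lag") <- 2L
    expect_equal(te_from_embedding(emb1, est, ts, source = 1),
                 te_from_embedding(emb2, est, ts, source = 1),
                 tolerance = 1e-12)
  }
})

test_that("delimited round trips preserve data in both orientations", {
  set.seed(1)
  ts <- ts_set(matrix(round(rnorm(2 * 30), 6), 2, 30), labels = c("a", "b"))
  f <- tempfile(fileext = ".csv")
  write_ts_delim(ts, f)
  expect_equal(read_ts_delim(f)$data, ts$data, ignore_attr = TRUE)
  write_ts_delim(ts, f, orientation = "columns", header = TRUE)
  back <- read_ts_delim(f, orientation = "columns", header = TRUE)
  expect_equal(back$data, ts$data, ignore_attr = TRUE)
  expect_equal(back$labels, c("a", "b"))

  writeLines(c("1,2,NA", "4,5,6"), f)
  expect_error(read_ts_delim(f), "NA")
})

test_that("integer downsampling keeps every k-th sample", {
  ts <- ts_set(matrix(1:20, 1))
  expect_equal(downsample_ts(ts, 4)$data[1, ], c(1, 5, 9, 13, 17))
})
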