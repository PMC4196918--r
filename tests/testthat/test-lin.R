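test_that("least-squares fit handles exact, null and stochastic designs", {
  x <- c(1, 2, 3, 4, 5)
  f <- lin_fit(2 * x, matrix(x))
  expect_equal(f$coefficients, 2)
  expect_lt(f$sigma2, 1e-20)

  y <- c(1, -1, 2, -2)
  f0 <- lin_fit(y, NULL)
  expect_equal(f0$sigma2, mean(y^2))

  set.seed(11)
  n <- 1000
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  fit <- lin_fit(x[-1], matrix(x[-n]))
  se <- sqrt(fit$sigma2 / sum(x[-n]^2))
  expect_lt(abs(fit$coefficients - 0.5), 3 * se)

  expect_warning(lin_fit(rnorm(10), cbind(1:10, 2 * (1:10))), "rank")
})

test_that("linear TE is zero for identical models and matches the population Granger ratio", {
  set.seed(3)
  y <- rnorm(100); X <- matrix(rnorm(200), 100, 2)
  expect_identical(lin_te(y, X, X), 0)

  # bivariate VAR(1) with known coefficients: estimate vs the closed-form
  # log-variance ratio computed from the generating model
  A <- matrix(c(0.5, 0, 0.4, 0.6), 2, 2, byrow = TRUE)  # x drives y
  te_true <- oracle_var1_te(A)
  expect_gt(te_true, 0.05)
  set.seed(21)
  dat <- simulate_var1(A, 20000)
  yv <- dat[2, -1]
  Xf <- cbind(dat[1, -ncol(dat)], dat[2, -ncol(dat)])
  Xr <- Xf[, 2, drop = FALSE]
  expect_equal(lin_te(yv, Xf, Xr), te_true, tolerance = 0.01)

  # nested designs: TE non-negative up to numerical noise
  set.seed(4)
  yy <- rnorm(300); XX <- matrix(rnorm(900), 300, 3)
  expect_gte(lin_te(yy, XX, XX[, 1:2]), -1e-12)
})

test_that("the null distribution of the extra-regressor TE matches F-test theory", {
  set.seed(8)
  n <- 512; reps <- 100
  tes <- numeric(reps); rej <- logical(reps)
  for (r in seq_len(reps)) {
    y <- rnorm(n); X <- matrix(rnorm(n), n, 1)
    fu <- lin_fit(y, X)
    fr <- lin_fit(y, NULL)
    tes[r] <- 0.5 * log(fr$rss / fu$rss)
    rej[r] <- f_test_lin_ue(fr$rss, fu$rss, 1, n, 1, alpha = 0.05)$significant
  }
  # TE of one spurious regressor is O(1/n): E = E[-0.5 log(1 - chisq_1/n)] ~ 1/(2n)
  expect_lt(mean(tes), 3 / n)
  expect_gt(mean(tes), 0)
  binom_sd <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * binom_sd)
})

test_that("BIC selects the generating order", {
  set.seed(5)
  hits <- 0L
  for (r in 1:10) {
    x <- as.numeric(arima.sim(list(ar = c(0.5, -0.4)), 1024))
    hits <- hits + (select_order_bic(ts_set(x), 5) == 2L)
  }
  expect_gte(hits, 9L)

  set.seed(6)
  expect_equal(select_order_bic(ts_set(rnorm(512)), 5), 1L)
  expect_equal(select_order_bic(ts_set(rnorm(512)), 1), 1L)
})

test_that("the F-test follows its arithmetic and rejects non-nested inputs", {
  v0 <- f_test_lin_ue(1, 1, 1, 100, 2)
  expect_equal(v0$statistic, 0)
  expect_false(v0$significant)

  v <- f_test_lin_ue(2, 1, 1, 102, 2, alpha = 0.05)
  expect_equal(v$statistic, 100)
  expect_true(v$significant)
  expect_equal(v$threshold, qf(0.95, 1, 100))

  expect_error(f_test_lin_ue(0.5, 1, 1, 100, 2), "non-nested")
  expect_error(f_test_lin_ue(2, 0, 1, 100, 2), "positive")
})

test_that("linear TE is invariant to affine rescaling of any series", {
  set.seed(81)
  ts <- ts_set(matrix(rnorm(3 * 256), 3, 256))
  emb <- embedding(2, data.frame(series = c(2, 1, 3), lag = c(1, 1, 2)))
  attr(emb, "anchor_lag") <- 2L
  est <- estimator_config("lin")
  te1 <- te_from_embedding(emb, est, ts, 1)
  scaled <- ts_set(ts$data * c(-7, 100, 0.01) + c(3, -2, 5))
  expect_equal(te_from_embedding(emb, est, scaled, 1), te1, tolerance = 1e-9)
})
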