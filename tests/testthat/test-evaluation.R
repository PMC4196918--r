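test_that("bivariate analysis reduces to unconditioned TE over both directions", {
  set.seed(61)
  ts <- simulate_coupled_maps(256)
  res <- analyze_ts(ts, "bin_ue", max_lag = 1, n_null = 30)
  expect_true(is.na(res$te[1, 1]) && is.na(res$te[2, 2]))
  expect_equal(sum(!is.na(res$te)), 2L)
})

test_that("five-variable batches evaluate all 20 directed pairs deterministically", {
  reals <- simulate_batch("linear_ar5", n = 192, n_realizations = 2, seed = 62)
  b1 <- run_batch(reals, "lin_ue", seed = 63, max_lag = 3)
  expect_equal(sum(!is.na(b1$te[1, , ])), 20L)
  b2 <- run_batch(reals, "lin_ue", seed = 63, max_lag = 3)
  expect_identical(b1$te, b2$te)
  expect_identical(b1$sig, b2$sig)

  expect_error(run_batch(reals, "magic"), "arg")
  expect_error(run_batch(list(reals[[1]], simulate_coupled_maps(192)), "lin_ue"),
               "shape")
})

test_that("significant-realization counting and pooled rates follow their accounting identities", {
  truth <- ground_truth("linear_ar5")
  R <- 4L; M <- 5L
  sig <- array(FALSE, c(R, M, M))
  te <- array(0, c(R, M, M))
  batch <- structure(list(te = te, sig = sig, method = "stub", truth = truth),
                     class = "mvte_batch")
  # always-null detector: sensitivity 0, specificity 1
  ss0 <- pooled_sens_spec(batch)
  expect_equal(ss0$sensitivity, 0)
  expect_equal(ss0$specificity, 1)
  expect_equal(count_significant(batch, 1, 2), 0L)
  expect_error(count_significant(batch, 2, 2), "diagonal")

  # perfect detector: flags exactly the true links in every realization
  A <- truth_adjacency(truth)
  for (r in seq_len(R)) batch$sig[r, , ] <- A
  ss1 <- pooled_sens_spec(batch)
  expect_equal(ss1$sensitivity, 1)
  expect_equal(ss1$specificity, 1)
  expect_equal(count_significant(batch, 1, 2), R)
  # pooled counts partition realizations x pairs
  expect_equal(ss1$tp + ss1$fn, R * 5)
  expect_equal(ss1$tn + ss1$fp, R * 15)

  rep <- link_report(batch)
  expect_equal(nrow(rep), 20L)
  expect_equal(sum(rep$truth), 5L)
  expect_equal(rep$n_sig[rep$truth], rep(R, 5))
})

test_that("length sweeps report one operating point per length", {
  sw <- roc_sweep("linear_ar5", "lin_ue", lengths = c(128L, 256L),
                  n_realizations = 2, seed = 64, max_lag = 3)
  expect_equal(sw$length, c(128L, 256L))
  expect_true(all(sw$sensitivity >= 0 & sw$sensitivity <= 1))
  expect_true(all(sw$specificity >= 0 & sw$specificity <= 1))
})

test_that("instantaneous driver terms are usable when the convention permits them", {
  set.seed(65)
  n <- 400
  x <- rnorm(n)
  y <- 0.9 * x + 0.5 * rnorm(n)   # same-sample influence 1 -> 2 only
  ts <- ts_set(rbind(x, y))
  res0 <- analyze_ts(ts, "lin_ue", max_lag = 2, est = estimator_config("lin", order = 2))
  expect_false(res0$sig[1, 2])    # invisible without lag-0 candidates
  res1 <- analyze_ts(ts, "lin_ue", max_lag = 2, instantaneous = 1,
                     est = estimator_config("lin", order = 2))
  expect_true(res1$sig[1, 2])
  expect_gt(res1$te[1, 2], 0.1)

  # the target itself never receives lag-0 terms
  cs <- build_candidate_set(2, 2, instantaneous = 1, target = 2)
  expect_false(any(cs$series == 2 & cs$lag == 0))
})
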