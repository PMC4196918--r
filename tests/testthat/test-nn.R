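test_that("nearest-neighbor entropy recovers the Gaussian closed form", {
  set.seed(16)
  h <- nn_entropy(rnorm(2000), k = 10)
  expect_lt(abs(h - 0.5 * log(2 * pi * exp(1))), 0.05)

  # scale covariance: H(aX) = H(X) + log a
  set.seed(17)
  x <- rnorm(1500)
  expect_lt(abs(nn_entropy(3 * x, k = 10) - nn_entropy(x, k = 10) - log(3)),
            0.05)

  expect_error(nn_entropy(rep(1, 50), k = 5), "duplicate")
})

test_that("the pruned-search CMI agrees exactly with a dist-matrix oracle", {
  set.seed(18)
  n <- 60
  y <- rnorm(n)
  C <- matrix(rnorm(n), n, 1)
  S <- matrix(rnorm(2 * n), n, 2)
  expect_equal(nn_cmi(y, C, S, k = 5), oracle_nn_cmi(y, C, S, k = 5),
               tolerance = 1e-12)
  expect_equal(nn_cmi(y, C, NULL, k = 5),
               oracle_nn_cmi(y, C, NULL, k = 5), tolerance = 1e-12)
  expect_equal(nn_cmi(y, C, S, k = 5, norm = "euclidean"),
               oracle_nn_cmi(y, C, S, k = 5, norm = "euclidean"),
               tolerance = 1e-12)
  # multi-column candidate block
  C2 <- cbind(C, rnorm(n))
  expect_equal(nn_cmi(y, C2, NULL, k = 5), oracle_nn_cmi(y, C2, NULL, k = 5),
               tolerance = 1e-12)
})

test_that("mutual information matches the Gaussian closed form and vanishes under independence", {
  rho <- 0.6
  mi_true <- -0.5 * log(1 - rho^2)
  set.seed(19)
  x <- rnorm(2000); z <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
  expect_lt(abs(nn_cmi(z, x, k = 10) - mi_true), 0.05)

  set.seed(20)
  mis <- replicate(20, nn_cmi(rnorm(512), rnorm(512), k = 10))
  expect_lt(abs(mean(mis)), 3 * sd(mis) / sqrt(20) + 0.01)
})

test_that("conditioning removes chain-mediated information", {
  # y <- s <- c: given s, c carries no extra information about y
  set.seed(22)
  below <- 0L
  for (r in 1:8) {
    n <- 400
    cvar <- rnorm(n)
    svar <- 0.8 * cvar + 0.6 * rnorm(n)
    yvar <- 0.8 * svar + 0.6 * rnorm(n)
    stat <- nn_cmi(yvar, cvar, matrix(svar), k = 10)
    nulls <- candidate_null(estimator_config("nn"), yvar, cvar, matrix(svar),
                            n_null = 40)
    below <- below + (stat <= sort(nulls)[38])
  }
  expect_gte(below, 6L)  # indistinguishable from the shuffle null
})

test_that("a copied target dominates every shuffle null", {
  set.seed(23)
  y <- rnorm(300)
  stat <- nn_cmi(y, y, k = 10)
  nulls <- candidate_null(estimator_config("nn"), y, y, NULL, n_null = 50)
  expect_true(all(stat > nulls))
})

test_that("NN and LIN transfer entropies agree on coupled Gaussian data", {
  A <- matrix(c(0.5, 0, 0.4, 0.6), 2, 2, byrow = TRUE)
  te_true <- oracle_var1_te(A)
  set.seed(24)
  dat <- simulate_var1(A, 2000)
  n <- ncol(dat)
  yv <- dat[2, -1]
  xs <- matrix(dat[1, -n]); xr <- matrix(dat[2, -n])
  te_lin <- lin_te(yv, cbind(xs, xr), xr)
  te_nn <- nn_te(yv, xs, xr, k = 10)
  expect_lt(abs(te_lin - te_true), 0.02)
  expect_lt(abs(te_nn - te_true), 0.05)
})
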