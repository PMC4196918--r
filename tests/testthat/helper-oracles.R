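# Independent brute-force oracles used to pin down expected values.

# plug-in entropy by dictionary counting over pasted rows
oracle_bin_entropy <- function(cols) {
  cols <- as.matrix(cols)
  key <- apply(cols, 1L, paste, collapse = "\r")
  p <- table(key) / length(key)
  -sum(p * log(p))
}

oracle_bin_ce <- function(y, X) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(oracle_bin_entropy(matrix(y)))
  oracle_bin_entropy(cbind(y, X)) - oracle_bin_entropy(X)
}

# dist-matrix implementation of the shared-radius digamma CMI
oracle_nn_cmi <- function(y, C, S = NULL, k = 10L, norm = "maximum") {
  C <- as.matrix(C)
  if (is.null(S)) S <- matrix(0, length(y), 0L)
  S <- as.matrix(S)
  n <- length(y)
  dmat <- function(m) {
    if (ncol(m) == 0L) return(matrix(0, n, n))
    as.matrix(stats::dist(m, method = norm))
  }
  D <- dmat(cbind(y, C, S)); diag(D) <- Inf
  eps <- apply(D, 1L, function(r) sort(r)[k])
  dS <- dmat(S); dyS <- dmat(cbind(y, S)); dcS <- dmat(cbind(C, S))
  acc <- 0
  for (i in seq_len(n)) {
    nS <- sum(dS[i, -i] < eps[i])
    nyS <- sum(dyS[i, -i] < eps[i])
    ncS <- sum(dcS[i, -i] < eps[i])
    acc <- acc + digamma(nS + 1) - digamma(nyS + 1) - digamma(ncS + 1)
  }
  digamma(k) + acc / n
}

# Stationary covariance of a VAR(1) x_t = A x_{t-1} + w, Cov(w) = Q,
# by solving the discrete Lyapunov equation exactly.
lyapunov_cov <- function(A, Q) {
  d <- nrow(A)
  vecS <- solve(diag(d * d) - kronecker(A, A), as.numeric(Q))
  matrix(vecS, d, d)
}

# Population Granger log-variance ratio for a bivariate VAR(1) with lag-1
# embedding: TE(x -> y) = 0.5 * log(Var(y_n | y_{n-1}) / Var(y_n | y_{n-1}, x_{n-1}))
oracle_var1_te <- function(A, Q = diag(2)) {
  S <- lyapunov_cov(A, Q)           # Cov of (x_t, y_t)
  # Cov of z = (x_t, y_t, x_{t-1}, y_{t-1})
  C01 <- A %*% S                    # Cov(x_t, x_{t-1}) block = A S
  big <- rbind(cbind(S, C01), cbind(t(C01), S))
  cond_var <- function(idx_y, idx_c) {
    big[idx_y, idx_y] - big[idx_y, idx_c, drop = FALSE] %*%
      solve(big[idx_c, idx_c]) %*% big[idx_c, idx_y, drop = FALSE]
  }
  v_r <- cond_var(2L, 4L)           # y_t | y_{t-1}
  v_u <- cond_var(2L, 3:4)          # y_t | x_{t-1}, y_{t-1}
  0.5 * as.numeric(log(v_r / v_u))
}

simulate_var1 <- function(A, n, burn = 500L) {
  d <- nrow(A)
  x <- matrix(0, d, n + burn)
  for (t in 2:(n + burn)) x[, t] <- A %*% x[, t - 1L] + rnorm(d)
  x[, (burn + 1L):(n + burn), drop = FALSE]
}

offdiag_idx <- function(M) which(row(diag(M)) != col(diag(M)))
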