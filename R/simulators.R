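# Benchmark system coefficients.
#
# Linear five-variable Gaussian AR network: a resonant AR(2) oscillator
# driving three chains, with a feedback pair; unit-variance Gaussian
# innovations. Directed couplings: 1->2 (lag 2), 1->3 (lag 3), 1->4 (lag 2),
# 4->5 and 5->4 (lag 1).
.ar5_a1 <- 0.95 * sqrt(2)   # x1 on its own lag 1
.ar5_a2 <- -0.9025          # x1 on its own lag 2
.ar5_c12 <- 0.5             # x1(n-2) -> x2
.ar5_c13 <- -0.4            # x1(n-3) -> x3
.ar5_c14 <- -0.5            # x1(n-2) -> x4
.ar5_c45 <- 0.25 * sqrt(2)  # x4/x5 feedback weight (lag 1)
# Non-linear variant: the 1->2 coupling acts through the squared driver
# sample, which carries no linear correlation with the (symmetric) driver
# process and is therefore invisible to a linear model while remaining a
# strong nonlinear dependence; the rest of the skeleton is unchanged.
#
# Coupled chaotic quadratic maps (noisy logistic-family map 1 - 1.8 x^2):
# unidirectional influence 1->2 at lag 1 through convex-combination coupling.
.map_a <- 1.8

#' Ground-truth coupling graph of a benchmark system
#'
#' @param system `"coupled_maps"`, `"linear_ar5"` or `"nonlinear_ar5"`.
#' @return list with `edges` (two-column matrix of directed from/to pairs,
#'   1-based), `M` (number of series) and `max_lag` (largest interaction lag).
#' @examples
#' ground_truth("linear_ar5")$edges
#' @export
ground_truth <- function(system = c("coupled_maps", "linear_ar5", "nonlinear_ar5")) {
  system <- match.arg(system)
  if (system == "coupled_maps") {
    list(edges = cbind(from = 1L, to = 2L), M = 2L, max_lag = 1L)
  } else {
    list(edges = cbind(from = c(1L, 1L, 1L, 4L, 5L), to = c(2L, 3L, 4L, 5L, 4L)),
         M = 5L, max_lag = 3L)
  }
}

#' Adjacency matrix of a ground-truth graph
#'
#' @param truth a [ground_truth()] list.
#' @return logical `M x M` matrix, `[i, j]` meaning `i -> j`.
#' @export
truth_adjacency <- function(truth) {
  A <- matrix(FALSE, truth$M, truth$M)
  A[truth$edges] <- TRUE
  A
}

# innovation-driven iteration with a divergence guard and bounded reseeding
.simulate_guarded <- function(n, burn_in, init_fn, step_fn, max_retries = 5L) {
  total <- n + burn_in
  for (attempt in 0:max_retries) {
    x <- init_fn(total)
    ok <- TRUE
    for (t in seq(x$t0, total)) {
      x <- step_fn(x, t)
      if (any(!is.finite(x$data[, t])) || any(abs(x$data[, t]) > 1e6)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(x$data[, (burn_in + 1L):total, drop = FALSE])
    # divergent trajectory: draw a fresh start from the session RNG
  }
  stop("simulation diverged after ", max_retries, " retries")
}

#' Simulate the coupled chaotic maps
#'
#' Two noisy quadratic maps with unidirectional coupling `1 -> 2` at lag 1:
#' \deqn{x_1(n) = 1 - 1.8 x_1(n-1)^2 + c\,\eta_1(n)}
#' \deqn{x_2(n) = (1-\epsilon)(1 - 1.8 x_2(n-1)^2) +
#'       \epsilon (1 - 1.8 x_1(n-1)^2) + c\,\eta_2(n)}
#' with Gaussian innovations \eqn{\eta}. With `coupling = 0` the two series
#' are statistically independent.
#'
#' @param n number of retained samples.
#' @param coupling coupling coefficient \eqn{\epsilon} in `[0, 1]`.
#' @param noise_coeff noise amplitude `c` (>= 0).
#' @param burn_in transient samples discarded before the first retained one.
#' @return an `mvte_ts` with 2 series.
#' @export
simulate_coupled_maps <- function(n = 512L, coupling = 0.3, noise_coeff = 0.01,
                                  burn_in = 1000L) {
  stopifnot(coupling >= 0, coupling <= 1, noise_coeff >= 0, burn_in >= 100L)
  f <- function(v) 1 - .map_a * v^2
  dat <- .simulate_guarded(
    n, burn_in,
    init_fn = function(total) {
      d <- matrix(0, 2L, total)
      d[, 1L] <- stats::runif(2L, -0.5, 0.5)
      list(data = d, t0 = 2L)
    },
    step_fn = function(x, t) {
      e <- stats::rnorm(2L)
      x$data[1L, t] <- f(x$data[1L, t - 1L]) + noise_coeff * e[1L]
      x$data[2L, t] <- (1 - coupling) * f(x$data[2L, t - 1L]) +
        coupling * f(x$data[1L, t - 1L]) + noise_coeff * e[2L]
      x
    })
  ts_set(dat, labels = c("x1", "x2"))
}

.simulate_ar5 <- function(n, burn_in, nonlinear) {
  c12 <- .ar5_c12; c13 <- .ar5_c13; c14 <- .ar5_c14
  c45 <- .ar5_c45; a1 <- .ar5_a1; a2 <- .ar5_a2
  sq <- if (nonlinear) function(v) v^2 else identity
  dat <- .simulate_guarded(
    n, burn_in,
    init_fn = function(total) {
      d <- matrix(0, 5L, total)
      d[, 1:3] <- stats::rnorm(15L)
      list(data = d, t0 = 4L)
    },
    step_fn = function(x, t) {
      d <- x$data
      w <- stats::rnorm(5L)
      x$data[1L, t] <- a1 * d[1L, t - 1L] + a2 * d[1L, t - 2L] + w[1L]
      x$data[2L, t] <- c12 * sq(d[1L, t - 2L]) + w[2L]
      x$data[3L, t] <- c13 * d[1L, t - 3L] + w[3L]
      x$data[4L, t] <- c14 * d[1L, t - 2L] + c45 * d[4L, t - 1L] +
        c45 * d[5L, t - 1L] + w[4L]
      x$data[5L, t] <- -c45 * d[4L, t - 1L] + c45 * d[5L, t - 1L] + w[5L]
      x
    })
  ts_set(dat, labels = paste0("x", 1:5))
}

#' Simulate the five-variable linear Gaussian AR network
#'
#' Five jointly Gaussian autoregressive series with unit-variance Gaussian
#' innovations and directed couplings `1->2`, `1->3`, `1->4`, `4->5`, `5->4`
#' extending up to three samples into the past; node 1 is a resonant AR(2)
#' oscillator. The companion-form spectral radius is below one (stationary);
#' see [ar5_spectral_radius()].
#'
#' @inheritParams simulate_coupled_maps
#' @return an `mvte_ts` with 5 series.
#' @export
simulate_linear_ar5 <- function(n = 512L, burn_in = 1000L) {
  stopifnot(burn_in >= 100L)
  .simulate_ar5(n, burn_in, nonlinear = FALSE)
}

#' Simulate the five-variable non-linear AR network
#'
#' Same coupling graph and autoregressive skeleton as
#' [simulate_linear_ar5()], but the coupling from node 1 to node 2 acts
#' through the squared driver sample. Because the driver is a symmetric
#' linear process, its square is linearly uncorrelated with its past, so
#' this link is invisible to linear (Granger) analysis while remaining a
#' strong nonlinear dependence.
#'
#' @inheritParams simulate_coupled_maps
#' @return an `mvte_ts` with 5 series.
#' @export
simulate_nonlinear_ar5 <- function(n = 512L, burn_in = 1000L) {
  stopifnot(burn_in >= 100L)
  .simulate_ar5(n, burn_in, nonlinear = TRUE)
}

#' Spectral radius of the linear benchmark's companion matrix
#'
#' Stationarity check of the linear AR benchmark: the modulus of the largest
#' eigenvalue of the companion form of its coefficient matrices (strictly
#' below 1 for a stable system).
#'
#' @return numeric scalar.
#' @export
ar5_spectral_radius <- function() {
  A1 <- matrix(0, 5, 5); A2 <- matrix(0, 5, 5); A3 <- matrix(0, 5, 5)
  A1[1, 1] <- .ar5_a1
  A2[1, 1] <- .ar5_a2
  A2[2, 1] <- .ar5_c12
  A3[3, 1] <- .ar5_c13
  A2[4, 1] <- .ar5_c14
  A1[4, 4] <- .ar5_c45; A1[4, 5] <- .ar5_c45
  A1[5, 4] <- -.ar5_c45; A1[5, 5] <- .ar5_c45
  comp <- rbind(cbind(A1, A2, A3),
                cbind(diag(10), matrix(0, 10, 5)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a batch of realizations
#'
#' Draws `n_realizations` independent realizations of a benchmark system,
#' each from a seed derived from `seed` so that realization `r` of a batch
#' equals a fresh run with the `r`-th derived seed.
#'
#' @param system benchmark name, as in [ground_truth()].
#' @param n samples per realization.
#' @param n_realizations batch size.
#' @param seed integer base seed.
#' @param ... passed to the simulator (e.g. `coupling`, `noise_coeff`,
#'   `burn_in`).
#' @return list of `mvte_ts` with attribute `truth`.
#' @export
simulate_batch <- function(system = c("coupled_maps", "linear_ar5", "nonlinear_ar5"),
                           n = 512L, n_realizations = 100L, seed = 1L, ...) {
  system <- match.arg(system)
  fn <- switch(system, coupled_maps = simulate_coupled_maps,
               linear_ar5 = simulate_linear_ar5,
               nonlinear_ar5 = simulate_nonlinear_ar5)
  out <- lapply(seq_len(n_realizations), function(r) {
    set.seed(derive_seed(seed, r))
    fn(n = n, ...)
  })
  attr(out, "truth") <- ground_truth(system)
  attr(out, "system") <- system
  out
}

#' Derive a per-realization seed from a base seed
#'
#' Deterministic mixing that stays within the 32-bit integer range.
#'
#' @param seed base seed.
#' @param r realization index.
#' @export
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + r * 104729) %% 2147483563)
}
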