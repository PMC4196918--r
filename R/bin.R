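#' Quantize a normalized series into Q equal-width levels
#'
#' Coarse-grains the dynamics over `Q` amplitude levels, each of width
#' `(max - min) / Q` of the (normalized) series. Each sample is assigned
#' the index of the level it falls in (`0 .. Q-1`); the global maximum is
#' assigned to the top level so both extremes are occupied.
#'
#' @param x numeric series (normalized, non-constant).
#' @param Q number of quantization levels (>= 2).
#' @return integer vector of symbols in `0..Q-1`, with attributes `Q` and `r`
#'   (bin width).
#' @examples
#' quantize(c(0, 1, 2, 3), Q = 2)  # 0 0 1 1
#' @export
quantize <- function(x, Q) {
  Q <- as.integer(Q)
  if (Q < 2L) stop("Q must be >= 2")
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("constant series cannot be quantized")
  r <- (hi - lo) / Q
  sym <- pmin.int(as.integer(floor((x - lo) / r)), Q - 1L)
  attr(sym, "Q") <- Q
  attr(sym, "r") <- r
  sym
}

# Collapse integer symbol columns into one joint code per row. Codes are kept
# exact in doubles and re-factorized to 0..(#distinct-1) whenever the range
# would threaten exactness, so any number of columns is supported.
joint_code <- function(cols) {
  cols <- as.matrix(cols)
  n <- nrow(cols)
  code <- numeric(n)
  lev <- 1
  for (j in seq_len(ncol(cols))) {
    v <- as.numeric(cols[, j])
    nv <- max(v) + 1
    if (lev * nv > 2^52) {
      u <- unique(code)
      code <- match(code, u) - 1
      lev <- length(u)
    }
    code <- code * nv + v
    lev <- lev * nv
  }
  code
}

# Entropy in nats from a vector of joint codes.
code_entropy <- function(code) {
  n <- length(code)
  cnt <- tabulate(match(code, unique(code)))
  log(n) - sum(cnt * log(cnt)) / n
}

#' Plug-in entropy of quantized columns
#'
#' Shannon entropy `H = -sum p log p` in nats, with the probability of each
#' occupied hypercube estimated as the fraction of quantized vectors falling
#' into it (maximum-likelihood plug-in; no bias correction).
#'
#' @param cols integer matrix (or vector) of quantized symbols, one column
#'   per embedding coordinate.
#' @return entropy in nats, between 0 and `d * log(Q)`.
#' @export
bin_entropy <- function(cols) {
  cols <- as.matrix(cols)
  if (nrow(cols) == 0L) stop("empty input")
  if (ncol(cols) == 0L) return(0)
  code_entropy(joint_code(cols))
}

#' Plug-in conditional entropy H(y | X)
#'
#' `CE = H(y, X) - H(X)` with both terms from [bin_entropy()]. With no
#' conditioning columns this is the marginal entropy of `y`. Non-negative
#' and never larger than `H(y)`; conditioning on additional columns can only
#' decrease it (a property of the plug-in estimate).
#'
#' @param y quantized target symbols.
#' @param X quantized conditioning columns (matrix, possibly 0 columns).
#' @return conditional entropy in nats.
#' @export
bin_ce <- function(y, X = NULL) {
  if (is.null(X)) X <- matrix(integer(0), length(y), 0L)
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(bin_entropy(y))
  cx <- joint_code(X)
  cyx <- joint_code(cbind(as.numeric(y), cx))
  code_entropy(cyx) - code_entropy(cx)
}

#' @export
est_columns.mvte_est_bin <- function(est, x) as.integer(quantize(x, est$Q))

#' @export
est_ce.mvte_est_bin <- function(est, y, X) bin_ce(y, X)

#' @export
est_score.mvte_est_bin <- function(est, y, cand, S) {
  -bin_ce(y, cbind(S, cand))
}

#' @export
est_null_kind.mvte_est_bin <- function(est) "time_shift"
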