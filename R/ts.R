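#' Construct a set of jointly observed time series
#'
#' Container for `M` named stationary series of equal length `N`, stored as an
#' `M x N` matrix (one series per row). All estimators and embedding
#' strategies in the package operate on this object.
#'
#' @param data numeric matrix (`M` series x `N` samples) or a vector for a
#'   single series.
#' @param labels optional character vector of series names; defaults to
#'   `"V1".."VM"` or existing rownames.
#' @param normalized logical, whether the series are already standardized.
#' @return An object of class `mvte_ts` with elements `data`, `labels`,
#'   `normalized`.
#' @examples
#' ts <- ts_set(rbind(sin(1:100), cos(1:100)), labels = c("x", "y"))
#' ts$labels
#' @export
ts_set <- function(data, labels = NULL, normalized = FALSE) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) stop("each series must have at least 2 samples")
  if (anyNA(data)) stop("time series data must not contain NA/NaN")
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("V", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) stop("one label per series required")
  rownames(data) <- labels
  structure(list(data = data, labels = labels, normalized = isTRUE(normalized)),
            class = "mvte_ts")
}

#' @export
print.mvte_ts <- function(x, ...) {
  cat(sprintf("<mvte_ts> %d series x %d samples%s\n", nrow(x$data),
              ncol(x$data), if (x$normalized) " (normalized)" else ""))
  cat("  series:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

n_series <- function(ts) nrow(ts$data)
n_samples <- function(ts) ncol(ts$data)

#' Standardize each series to zero mean and unit variance
#'
#' Per-series standardization using the population (1/N) variance convention.
#' Idempotent: normalizing an already-normalized set returns it unchanged (up
#' to floating point). Constant series cannot be standardized and raise an
#' error naming the offending series.
#'
#' @param ts an [ts_set()] object.
#' @return A normalized `mvte_ts`.
#' @export
normalize_ts <- function(ts) {
  stopifnot(inherits(ts, "mvte_ts"))
  x <- ts$data
  n <- ncol(x)
  mu <- rowMeans(x)
  cent <- x - mu
  v <- rowMeans(cent^2)  # population variance
  bad <- which(v == 0)
  if (length(bad))
    stop("constant series cannot be normalized: ",
         paste(ts$labels[bad], collapse = ", "))
  ts$data <- cent / sqrt(v)
  rownames(ts$data) <- ts$labels
  ts$normalized <- TRUE
  ts
}

#' Read a delimited time-series matrix
#'
#' Reads CSV/TSV text with either one series per row (default, matching the
#' package's internal layout) or one series per column. `NA`/`NaN` values are
#' rejected.
#'
#' @param path file path.
#' @param sep field separator; `","` default, use `"\t"` for TSV.
#' @param orientation `"rows"` if each row is a series, `"columns"` otherwise.
#' @param header logical, whether the file carries series names.
#' @return An `mvte_ts`.
#' @export
read_ts_delim <- function(path, sep = ",", orientation = c("rows", "columns"),
                          header = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = sep, header = header && orientation == "columns",
                          row.names = NULL, stringsAsFactors = FALSE)
  if (orientation == "rows") {
    labels <- NULL
    if (header) {
      labels <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    } else if (!all(vapply(df, is.numeric, logical(1L)))) {
      # tolerate an unannounced leading label column
      labels <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    }
    m <- as.matrix(df)
  } else {
    labels <- if (header) colnames(df) else NULL
    m <- t(as.matrix(df))
  }
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (anyNA(m)) stop("NA/NaN values in ", path)
  dimnames(m) <- NULL
  ts_set(m, labels = labels)
}

#' Write a time-series set as delimited text
#'
#' @param ts an `mvte_ts`.
#' @param path output file path.
#' @param sep field separator.
#' @param orientation layout, as in [read_ts_delim()].
#' @param header write series labels.
#' @export
write_ts_delim <- function(ts, path, sep = ",",
                           orientation = c("rows", "columns"), header = FALSE) {
  orientation <- match.arg(orientation)
  m <- ts$data
  if (orientation == "rows") {
    utils::write.table(m, path, sep = sep, row.names = header,
                       col.names = FALSE, quote = FALSE)
  } else {
    tm <- t(m)
    colnames(tm) <- ts$labels
    utils::write.table(tm, path, sep = sep, row.names = FALSE,
                       col.names = header, quote = FALSE)
  }
  invisible(path)
}

#' Keep every k-th sample of each series
#'
#' Integer downsampling pass-through for data recorded at a higher rate than
#' the dynamics of interest. No filtering is applied.
#'
#' @param ts an `mvte_ts`.
#' @param factor positive integer decimation factor.
#' @export
downsample_ts <- function(ts, factor) {
  stopifnot(inherits(ts, "mvte_ts"), factor >= 1, factor == as.integer(factor))
  if (factor == 1L) return(ts)
  ts$data <- ts$data[, seq(1L, ncol(ts$data), by = as.integer(factor)), drop = FALSE]
  ts$normalized <- FALSE
  ts
}
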