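#' @keywords internal
#' @useDynLib mvte, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qf pf rnorm runif sd cor quantile
#' @importFrom utils read.table write.table
"_PACKAGE"
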