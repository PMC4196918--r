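#' Assemble a run configuration
#'
#' A declarative description of one analysis run: where the data live, which
#' channels to use, which methods to run on which target/driver pairs, and
#' the significance settings. Validate with [validate_config()], execute with
#' [run_experiment()].
#'
#' @param data_dir directory of delimited data files (one realization each).
#' @param data_pattern filename glob for realizations.
#' @param sep,orientation,header delimited-format options
#'   (see [read_ts_delim()]).
#' @param channels series indices to retain (default all).
#' @param downsample integer decimation factor.
#' @param end_point optional cut: keep only samples `1..end_point`.
#' @param methods character vector of [mvte_methods()] names.
#' @param max_lag maximum candidate lag.
#' @param all_pairs if `TRUE` every ordered pair is analyzed; otherwise
#'   `targets` and `drivers` give explicit pair rows.
#' @param targets,drivers equal-length index vectors of explicit pairs
#'   (ignored when `all_pairs`).
#' @param instantaneous series whose lag-0 sample may enter other targets'
#'   embeddings.
#' @param Q,k,norm estimator parameters.
#' @param alpha,n_null,min_shift significance parameters.
#' @param seed base seed.
#' @param out_dir output directory.
#' @return list of class `mvte_config`.
#' @export
run_config <- function(data_dir, data_pattern = "*.csv", sep = ",",
                       orientation = "rows", header = FALSE, channels = NULL,
                       downsample = 1L, end_point = NULL,
                       methods = "bin_nue", max_lag = 5L, all_pairs = TRUE,
                       targets = integer(0), drivers = integer(0),
                       instantaneous = integer(0), Q = 6L, k = 10L,
                       norm = "max", alpha = 0.05, n_null = 100L,
                       min_shift = 20L, seed = 1L, out_dir = "mvte_out") {
  structure(as.list(environment()), class = "mvte_config")
}

#' Validate a run configuration
#'
#' @param config an [run_config()] object.
#' @return character vector of issues; empty when the configuration is
#'   runnable. Each issue names the offending key.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!all(config$methods %in% mvte_methods()))
    add(sprintf("methods: unknown method(s) %s",
                paste(setdiff(config$methods, mvte_methods()), collapse = ", ")))
  if (config$max_lag < 1) add("max_lag: must be >= 1")
  if (config$Q < 2) add("Q: must be >= 2")
  if (config$k < 1) add("k: must be >= 1")
  if (!(config$alpha > 0 && config$alpha < 1)) add("alpha: must be in (0, 1)")
  if (config$n_null < 20) add("n_null: must be >= 20")
  if (config$min_shift < 1) add("min_shift: must be >= 1")
  if (config$downsample < 1) add("downsample: must be >= 1")
  if (!config$all_pairs) {
    if (length(config$targets) != length(config$drivers))
      add("targets/drivers: must have equal length")
    if (any(config$targets == config$drivers))
      add("targets/drivers: a series cannot drive itself")
    if (any(config$targets %in% config$instantaneous))
      add("instantaneous: contains a target series")
  }
  if (!dir.exists(config$data_dir))
    add(sprintf("data_dir: '%s' does not exist", config$data_dir))
  issues
}

#' Execute a configured analysis run
#'
#' Reads every matching data file, applies channel selection, decimation and
#' end-point cuts, runs each requested method over all realizations, and
#' writes per-pair results (CSV), per-method summaries (JSON) and a run
#' manifest sufficient to reproduce the run.
#'
#' @param config an [run_config()]; must validate cleanly.
#' @return the manifest (invisibly), a list with the config snapshot, seeds,
#'   package version, timing and output index.
#' @export
run_experiment <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) stop("invalid config:\n  ", paste(issues, collapse = "\n  "))
  files <- sort(Sys.glob(file.path(config$data_dir, config$data_pattern)))
  if (!length(files)) stop("no data files match ", config$data_pattern)
  reals <- lapply(files, function(f) {
    ts <- read_ts_delim(f, sep = config$sep, orientation = config$orientation,
                        header = config$header)
    if (!is.null(config$channels)) {
      ts <- ts_set(ts$data[config$channels, , drop = FALSE],
                   labels = ts$labels[config$channels])
    }
    ts <- downsample_ts(ts, config$downsample)
    if (!is.null(config$end_point))
      ts <- ts_set(ts$data[, seq_len(config$end_point), drop = FALSE],
                   labels = ts$labels)
    ts
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- list()
  timing <- list()
  for (method in config$methods) {
    parts <- method_parts(method)
    est <- estimator_config(parts[1L], Q = config$Q, k = config$k,
                            norm = config$norm)
    t0 <- proc.time()[["elapsed"]]
    batch <- run_batch(reals, method, seed = config$seed, est = est,
                       max_lag = config$max_lag, alpha = config$alpha,
                       n_null = config$n_null, min_shift = config$min_shift,
                       instantaneous = config$instantaneous)
    timing[[method]] <- proc.time()[["elapsed"]] - t0
    rep <- link_report(batch)
    if (!config$all_pairs) {
      keep <- mapply(function(d, t) any(rep$from == d & rep$to == t),
                     config$drivers, config$targets)
      sel <- do.call(rbind, Map(function(d, t)
        rep[rep$from == d & rep$to == t, ], config$drivers, config$targets))
      rep <- sel
    }
    csv <- file.path(config$out_dir, paste0(method, "_links.csv"))
    utils::write.csv(rep, csv, row.names = FALSE)
    index[[method]] <- csv
  }
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("mvte")),
                   n_realizations = length(reals),
                   timing_seconds = timing, outputs = index)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
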