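#' Construct a trace set
#'
#' The common container for node response time series: a uniform time grid
#' plus one series per node. Produced by the integrators, by the synthetic
#' calcium-trace generator, and by [read_traces()]; consumed by the
#' synchrony metrics.
#'
#' @param times strictly increasing, uniformly spaced time grid.
#' @param values numeric matrix, one row per time point and one column per
#'   node. Column names become node ids (defaults `n1, n2, ...`).
#' @param period optional stimulus period associated with the record.
#' @return A list of class `"trace_set"` with elements `times`, `values`,
#'   `period`.
#' @export
trace_set <- function(times, values, period = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(times), is.numeric(values),
            nrow(values) == length(times), length(times) >= 2L)
  dts <- diff(times)
  if (any(dts <= 0)) stop("`times` must be strictly increasing")
  if (diff(range(dts)) > 1e-8 * mean(dts)) {
    stop("`times` must be uniformly spaced")
  }
  if (anyNA(values)) stop("trace values must not contain missing values")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("n", seq_len(ncol(values)))
  }
  structure(list(times = as.numeric(times), values = values, period = period),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d nodes x %d samples, dt = %g, span = %g%s\n",
              ncol(x$values), length(x$times), x$times[2] - x$times[1],
              x$times[length(x$times)] - x$times[1],
              if (is.null(x$period)) "" else sprintf(", period = %g", x$period)))
  invisible(x)
}

as_trace_matrix <- function(traces) {
  if (inherits(traces, "trace_set")) traces$values else as.matrix(traces)
}
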