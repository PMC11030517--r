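# Tabular text serialization: trace files carry a `time` column plus one
# column per node; spike files are (unit_id, spike_time) rows; pair lists
# are (node_i, node_j[, provenance]) rows.  Comma-separated, header row,
# '.' decimal, times in model units (or seconds for recordings).

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write a trace set to CSV
#'
#' @param traces a [trace_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- data.frame(time = fmt_num(traces$times))
  for (j in seq_len(ncol(traces$values))) {
    df[[colnames(traces$values)[j]]] <- fmt_num(traces$values[, j])
  }
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("failed writing traces to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a trace set from CSV
#'
#' Expects a `time` column plus one numeric column per node.
#'
#' @param path input file.
#' @param period optional stimulus period to attach.
#' @return A [trace_set()].
#' @export
read_traces <- function(path, period = NULL) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("failed parsing trace file '", path,
                                          "': ", conditionMessage(e)))
  if (!"time" %in% names(df)) {
    stop("trace file '", path, "' has no `time` column")
  }
  node_cols <- setdiff(names(df), "time")
  if (length(node_cols) == 0L) stop("trace file '", path, "' has no node columns")
  for (cn in c("time", node_cols)) {
    if (!is.numeric(df[[cn]])) {
      stop("trace file '", path, "': column `", cn, "` is not numeric")
    }
    if (anyNA(df[[cn]])) {
      stop("trace file '", path, "': column `", cn, "` contains missing values (row ",
           which(is.na(df[[cn]]))[1], ")")
    }
  }
  trace_set(df$time, as.matrix(df[node_cols]), period = period)
}

#' Write spike trains to CSV
#'
#' @param spikes list of spike-time vectors, one per unit (names become
#'   unit ids; default `n1, n2, ...`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  ids <- names(spikes)
  if (is.null(ids)) ids <- paste0("n", seq_along(spikes))
  df <- data.frame(unit_id = rep(ids, lengths(spikes)),
                   spike_time = fmt_num(unlist(spikes, use.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a neighbour-pair list from CSV
#'
#' Expects columns `node_i`, `node_j` and optionally `provenance`.
#'
#' @param path input file.
#' @return Data frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- tryCatch(read.csv(path),
                 error = function(e) stop("failed parsing pair file '", path,
                                          "': ", conditionMessage(e)))
  if (!all(c("node_i", "node_j") %in% names(df))) {
    stop("pair file '", path, "' needs columns `node_i`, `node_j`")
  }
  if (any(df$node_i == df$node_j)) {
    stop("pair file '", path, "': self-pair at row ",
         which(df$node_i == df$node_j)[1])
  }
  df
}

#' Write an adjacency edge list and node table
#'
#' @param lattice a `"lattice"`.
#' @param edge_path,node_path output files.
#' @return Invisibly, the two paths.
#' @export
write_lattice <- function(lattice, edge_path, node_path) {
  stopifnot(inherits(lattice, "lattice"))
  edges <- data.frame(node_i = lattice$edges[, 1], node_j = lattice$edges[, 2])
  write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  nodes <- lattice$nodes
  if (is.null(nodes$disrupted)) nodes$disrupted <- FALSE
  write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, node_path))
}
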