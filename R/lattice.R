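# Lattice construction.  Boundaries are non-periodic throughout: edge and
# corner nodes simply have fewer neighbours, matching a finite
# micropatterned field of view.

square_edge_candidates <- function(rows, cols) {
  id <- function(r, c) (r - 1L) * cols + c
  e <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) e[[length(e) + 1L]] <- c(id(r, c), id(r, c + 1L))
      if (r < rows) e[[length(e) + 1L]] <- c(id(r, c), id(r + 1L, c))
    }
  }
  do.call(rbind, e)
}

# Row-offset triangular embedding: node (r, c) neighbours (r, c±1),
# (r±1, c), and (r±1, c + (-1)^r), giving interior nodes six neighbours.
triangular_edge_candidates <- function(rows, cols) {
  id <- function(r, c) (r - 1L) * cols + c
  ok <- function(r, c) r >= 1L && r <= rows && c >= 1L && c <= cols
  e <- list()
  for (r in seq_len(rows)) {
    off <- if (r %% 2L == 0L) 1L else -1L
    for (c in seq_len(cols)) {
      nb <- list(c(r, c + 1L), c(r + 1L, c), c(r + 1L, c + off))
      for (x in nb) {
        if (ok(x[1], x[2])) {
          e[[length(e) + 1L]] <- c(id(r, c), id(x[1], x[2]))
        }
      }
    }
  }
  do.call(rbind, e)
}

node_table <- function(rows, cols) {
  data.frame(node_id = seq_len(rows * cols),
             row = rep(seq_len(rows), each = cols),
             col = rep(seq_len(cols), rows))
}

#' Build a square lattice with probabilistic edges
#'
#' Nodes sit on a non-periodic `rows x cols` grid; each of the
#' `2*rows*cols - rows - cols` nearest-neighbour edges is included
#' independently with probability `p`, emulating micropatterned bridges
#' placed between adjacent nodes at connectivity `p`.
#'
#' @param rows,cols lattice dimensions, each >= 2.
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed for the edge draws.
#' @return A list of class `"lattice"`: `edges` (two-column matrix of node
#'   ids, `i < j`), `nodes` (data frame with `node_id`, `row`, `col`),
#'   `topology = "square"`, and the build parameters.
#' @examples
#' lat <- build_square_lattice(18, 18, p = 0.75, seed = 1)
#' nrow(lat$edges)  # ~ 0.75 * 612
#' @export
build_square_lattice <- function(rows, cols, p, seed = NULL) {
  stopifnot(rows >= 2, cols >= 2, p >= 0, p <= 1)
  cand <- square_edge_candidates(as.integer(rows), as.integer(cols))
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(nrow(cand)) < p
  structure(list(edges = cand[keep, , drop = FALSE],
                 nodes = node_table(rows, cols),
                 topology = "square", rows = rows, cols = cols,
                 p = p, seed = seed),
            class = "lattice")
}

#' Build a triangular lattice with node disruption
#'
#' Non-periodic six-neighbour triangular lattice in a row-offset embedding
#' (interior nodes have degree 6). Each node is independently disrupted with
#' probability `q`; a disrupted node loses all its gap-junction edges but
#' remains in the network and still receives the external drive (the drive
#' models bath-applied ATP, which reaches every cell).
#'
#' @param rows,cols lattice dimensions, each >= 2.
#' @param q disruption probability in `[0, 1]`.
#' @param seed integer seed for the disruption draws.
#' @return A list of class `"lattice"` as in [build_square_lattice()], with
#'   `topology = "triangular"`, a logical `disrupted` column in `nodes`,
#'   and `disrupted` (the disrupted node ids).
#' @export
build_triangular_lattice <- function(rows, cols, q, seed = NULL) {
  stopifnot(rows >= 2, cols >= 2, q >= 0, q <= 1)
  cand <- triangular_edge_candidates(as.integer(rows), as.integer(cols))
  nodes <- node_table(rows, cols)
  if (!is.null(seed)) set.seed(seed)
  disrupted <- runif(nrow(nodes)) < q
  nodes$disrupted <- disrupted
  keep <- !(disrupted[cand[, 1]] | disrupted[cand[, 2]])
  structure(list(edges = cand[keep, , drop = FALSE], nodes = nodes,
                 topology = "triangular", rows = rows, cols = cols,
                 q = q, seed = seed,
                 disrupted = which(disrupted)),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice> %s %dx%d, %d nodes, %d edges%s\n",
              x$topology, x$rows, x$cols, nrow(x$nodes), nrow(x$edges),
              if (x$topology == "triangular")
                sprintf(", %d disrupted", length(x$disrupted)) else ""))
  invisible(x)
}

#' Sample per-node heterogeneity on periods
#'
#' Draws intrinsic periods `tau_i ~ Normal(T, T/10)` — cell-to-cell
#' heterogeneity is specified on periods, not on `b` — and maps them through
#' [b_from_period()]. Draws at or below `T/100` (vanishingly rare at sd
#' `T/10`) are resampled to guard against non-positive periods.
#'
#' @param n_nodes number of nodes.
#' @param period mean intrinsic period `T`, > 0.
#' @param seed integer seed.
#' @param sd_frac sd as a fraction of `T` (default 1/10).
#' @return Numeric vector of drive parameters `b_i`.
#' @export
sample_heterogeneity <- function(n_nodes, period, seed = NULL, sd_frac = 0.1) {
  stopifnot(period > 0, n_nodes >= 1)
  if (!is.null(seed)) set.seed(seed)
  taus <- rnorm(n_nodes, mean = period, sd = sd_frac * period)
  bad <- taus <= period / 100
  while (any(bad)) {
    taus[bad] <- rnorm(sum(bad), mean = period, sd = sd_frac * period)
    bad <- taus <= period / 100
  }
  b_from_period(taus)
}

#' Assemble a driven network model
#'
#' Bundles a lattice, per-node drive parameters, and the coupling and drive
#' strengths into the network generalization of the driven pair:
#' `dv_i/dt = b_i + v_i^2 + sum_{j~i} g (v_j - v_i) + g0 (u - v_i)`.
#'
#' @param lattice a `"lattice"` from [build_square_lattice()] or
#'   [build_triangular_lattice()].
#' @param b_values per-node drive parameters, one per lattice node.
#' @param g cell-cell coupling strength, >= 0.
#' @param g0 drive-to-cell coupling strength, >= 0.
#' @param b0 drive-unit parameter (use [b_from_period()] for a target
#'   period).
#' @param v_reset,v_peak reset thresholds shared by all cells.
#' @return A list of class `"network_model"`.
#' @export
network_model <- function(lattice, b_values, g, g0, b0,
                          v_reset = 0, v_peak = 1) {
  stopifnot(inherits(lattice, "lattice"),
            length(b_values) == nrow(lattice$nodes),
            g >= 0, g0 >= 0, b0 > 0, v_reset < v_peak)
  structure(list(lattice = lattice, b_values = as.numeric(b_values),
                 g = g, g0 = g0, b0 = b0,
                 v_reset = v_reset, v_peak = v_peak),
            class = "network_model")
}

#' Integrate a driven QIF network
#'
#' Every cell obeys
#' `dv_i/dt = b_i + v_i^2 + sum_{j~i} g (v_j - v_i) + g0 (u - v_i)` with an
#' independent per-cell reset; the drive `u` is the autonomous QIF unit of
#' [integrate_driven_pair()]. Runs for `n_periods` drive periods.
#'
#' @param model a [network_model()].
#' @param n_periods number of drive periods to simulate (default 8).
#' @param v0 initial voltages (default: uniform on `[v_reset, v_peak)`
#'   drawn from `seed`).
#' @param u0 initial drive state.
#' @param seed seed for default initial conditions.
#' @param cfg an [integrator_config()]; default step is (smallest intrinsic
#'   period)/1000.
#' @param record_every record every k-th step of the trace (spike times are
#'   always exact); the default keeps about 200 samples per drive period.
#' @return A list with `trace` ([trace_set()] of all cells), `drive`,
#'   `spikes` (per-cell list), `drive_spikes`.
#' @export
integrate_network <- function(model, n_periods = 8, v0 = NULL, u0 = 0,
                              seed = NULL, cfg = NULL, record_every = NULL) {
  stopifnot(inherits(model, "network_model"), n_periods >= 1)
  b <- model$b_values
  period <- qif_period(model$b0)
  t_end <- n_periods * period
  if (is.null(cfg)) {
    taus <- c(qif_period(b[b > 0]), period)
    cfg <- integrator_config(min(taus) / 1000)
  }
  if (is.null(v0)) {
    if (!is.null(seed)) set.seed(seed)
    v0 <- runif(length(b), model$v_reset, model$v_peak)
  }
  if (is.null(record_every)) {
    record_every <- max(1L, floor(period / cfg$dt / 200))
  }
  res <- run_core(b, model$lattice$edges, model$g, model$g0, model$b0,
                  v0, u0, model$v_reset, model$v_peak,
                  t_end, cfg$dt, cfg$method, record_every)
  list(trace = trace_set(res$times, res$v, period = period),
       drive = trace_set(res$times, matrix(res$u, dimnames = list(NULL, "u")),
                         period = period),
       spikes = res$spikes, drive_spikes = res$u_spikes)
}
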