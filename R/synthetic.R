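# Synthetic calcium-recording generator: stimulus-locked transient
# responses with Poisson-distributed onset delays, a rise/decay kernel,
# per-node amplitude heterogeneity, additive noise, and a micropattern-like
# grid layout with bridged neighbour pairs at probability p.  It emulates
# the statistics the analysis stage consumes — not the underlying
# IP3/calcium kinetics, and not gap-junction coupling (coupled dynamics
# come from the network simulator).

#' Square-wave stimulus series
#'
#' ON for `duty * period`, OFF for the rest, repeated `n_cycles` times on a
#' uniform sample grid. Emulates alternating ATP/growth-medium delivery at
#' 50% duty cycle.
#'
#' @param period stimulus period `T` (seconds).
#' @param duty ON fraction in (0, 1); default 0.5.
#' @param n_cycles number of repeats.
#' @param dt sample interval (seconds); `period/dt` must be >= 20.
#' @return Data frame with columns `time`, `stim` (0/1); the record spans
#'   `n_cycles * period`.
#' @export
make_stimulus <- function(period, duty = 0.5, n_cycles, dt = 1) {
  stopifnot(period > 0, duty > 0, duty < 1, n_cycles >= 1,
            period / dt >= 20)
  times <- seq(0, n_cycles * period - dt, by = dt)
  stim <- as.numeric((times %% period) < duty * period)
  data.frame(time = times, stim = stim)
}

#' Poisson stimulus-onset delays
#'
#' Node activation is delayed behind each stimulus onset by
#' `dt_ic ~ Poisson(alpha * T)` seconds, drawn independently per node and
#' per cycle, so that the delay variance grows linearly with the period
#' (`sigma^2 = alpha * T`) — the noise-integration mechanism behind the
#' `T^(-1/2)` deviation scaling. Delays are clipped to the ON half-cycle;
#' clips are counted in the `"n_clipped"` attribute.
#'
#' @param n_nodes,n_cycles matrix dimensions.
#' @param alpha rate scale (per second); the Poisson mean is `alpha * period`.
#' @param period stimulus period (seconds).
#' @param duty ON fraction used for clipping (default 0.5).
#' @param seed integer seed.
#' @return `n_nodes x n_cycles` matrix of delays in seconds.
#' @export
sample_delays <- function(n_nodes, n_cycles, alpha, period, duty = 0.5,
                          seed = NULL) {
  stopifnot(alpha > 0, period > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(rpois(n_nodes * n_cycles, lambda = alpha * period),
              nrow = n_nodes, ncol = n_cycles)
  lim <- duty * period
  n_clipped <- sum(d > lim)
  d[d > lim] <- lim
  structure(d, n_clipped = n_clipped)
}

# calcium-transient-like kernel: exponential rise and decay, peak scaled
# to 1.  K(s) = (1 - exp(-s/rise)) * exp(-s/decay) / K(s*), s >= 0.
transient_kernel <- function(s, rise, decay) {
  s_star <- rise * log(1 + decay / rise)
  peak <- (1 - exp(-s_star / rise)) * exp(-s_star / decay)
  out <- numeric(length(s))
  pos <- s >= 0
  out[pos] <- (1 - exp(-s[pos] / rise)) * exp(-s[pos] / decay) / peak
  out
}

#' Render calcium-like response traces
#'
#' Each node's response is a baseline of 1 (fold-change convention) plus a
#' sum over stimulus cycles of a rise/decay transient kernel shifted by
#' that node's per-cycle onset delay, scaled by a per-node amplitude, plus
#' additive Gaussian noise.
#'
#' @param stimulus output of [make_stimulus()].
#' @param period stimulus period used to locate cycle onsets.
#' @param delays delay matrix from [sample_delays()] (nodes x cycles).
#' @param kernel list with `rise`, `decay` (seconds, `rise < decay`) and
#'   `amp_sd` (per-node multiplicative amplitude sd). Defaults: 2 s rise,
#'   10 s decay, 10% amplitude heterogeneity.
#' @param noise_sd additive Gaussian noise sd (fold-change units, default
#'   0.01).
#' @param seed integer seed for amplitudes and noise.
#' @return A [trace_set()] with the stimulus period attached.
#' @export
render_traces <- function(stimulus, period, delays,
                          kernel = list(rise = 2, decay = 10, amp_sd = 0.1),
                          noise_sd = 0.01, seed = NULL) {
  stopifnot(kernel$rise > 0, kernel$decay > kernel$rise, noise_sd >= 0)
  times <- stimulus$time
  n_nodes <- nrow(delays)
  n_cycles <- ncol(delays)
  onsets <- (seq_len(n_cycles) - 1) * period
  if (!is.null(seed)) set.seed(seed)
  amps <- pmax(0.1, rnorm(n_nodes, 1, kernel$amp_sd))
  vals <- matrix(1, nrow = length(times), ncol = n_nodes)
  for (i in seq_len(n_nodes)) {
    resp <- numeric(length(times))
    for (c in seq_len(n_cycles)) {
      resp <- resp + transient_kernel(times - onsets[c] - delays[i, c],
                                      kernel$rise, kernel$decay)
    }
    vals[, i] <- vals[, i] + amps[i] * resp
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
  }
  colnames(vals) <- paste0("n", seq_len(n_nodes))
  trace_set(times, vals, period = period)
}

#' Generate a complete synthetic calcium-recording dataset
#'
#' Lays nodes on a `rows x cols` grid with the micropattern geometry
#' (20 um node radius, 30 um edge-to-edge gap, so a 70 um pitch), draws
#' bridged nearest-neighbour pairs at probability `p` (for `p = 0`, each
#' node is paired with one randomly sampled spatially nearest neighbour
#' instead, tagged `spatial_nearest`), and renders delayed, noisy transient
#' traces. Optionally writes the four dataset files.
#'
#' @param rows,cols grid dimensions.
#' @param p bridge probability in `[0, 1]`.
#' @param period,duty,n_cycles,dt stimulus parameters ([make_stimulus()]).
#' @param alpha delay rate scale ([sample_delays()]; default 0.05 /s).
#' @param kernel,noise_sd trace parameters ([render_traces()]).
#' @param seed master seed; pairs, delays, amplitudes and noise each use a
#'   child seed derived from it.
#' @param dir if non-NULL, write `traces.csv` (time + node columns),
#'   `layout.csv`, `pairs.csv`, and `manifest.json` there.
#' @return A list of class `"synthetic_dataset"`: `traces` ([trace_set()]),
#'   `layout`, `pairs`, `delays`, `stimulus`, `manifest`, and (when
#'   written) `files`.
#' @export
generate_dataset <- function(rows, cols, p, period, duty = 0.5, n_cycles = 8,
                             dt = 1, alpha = 0.05,
                             kernel = list(rise = 2, decay = 10, amp_sd = 0.1),
                             noise_sd = 0.01, seed = 1, dir = NULL) {
  stopifnot(p >= 0, p <= 1, rows >= 2, cols >= 2)
  n_nodes <- rows * cols
  seeds <- local({ set.seed(seed); sample.int(.Machine$integer.max - 1L, 3L) })

  pitch <- 2 * 20 + 30  # um, centre-to-centre
  layout <- node_table(rows, cols)
  layout$x_um <- (layout$col - 1) * pitch
  layout$y_um <- (layout$row - 1) * pitch

  cand <- square_edge_candidates(rows, cols)
  set.seed(seeds[1])
  if (p > 0) {
    keep <- runif(nrow(cand)) < p
    pairs <- data.frame(node_i = paste0("n", cand[keep, 1]),
                        node_j = paste0("n", cand[keep, 2]),
                        provenance = "bridged")
  } else {
    # one randomly sampled grid-nearest neighbour per node, de-duplicated
    pick <- t(vapply(seq_len(n_nodes), function(i) {
      nb <- c(cand[cand[, 1] == i, 2], cand[cand[, 2] == i, 1])
      j <- nb[sample.int(length(nb), 1)]
      as.integer(sort(c(i, j)))
    }, integer(2)))
    pick <- unique(pick)
    pairs <- data.frame(node_i = paste0("n", pick[, 1]),
                        node_j = paste0("n", pick[, 2]),
                        provenance = "spatial_nearest")
  }

  stimulus <- make_stimulus(period, duty, n_cycles, dt)
  delays <- sample_delays(n_nodes, n_cycles, alpha, period, duty,
                          seed = seeds[2])
  traces <- render_traces(stimulus, period, delays, kernel, noise_sd,
                          seed = seeds[3])

  manifest <- list(schema_version = 1L,
                   rows = rows, cols = cols, p = p,
                   period = period, duty = duty, n_cycles = n_cycles,
                   dt = dt, alpha = alpha,
                   kernel = kernel, noise_sd = noise_sd,
                   seed = seed, child_seeds = as.integer(seeds),
                   n_delay_clipped = attr(delays, "n_clipped"),
                   node_radius_um = 20, edge_gap_um = 30)

  out <- structure(list(traces = traces, layout = layout, pairs = pairs,
                        delays = delays, stimulus = stimulus,
                        manifest = manifest),
                   class = "synthetic_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(traces = file.path(dir, "traces.csv"),
               layout = file.path(dir, "layout.csv"),
               pairs = file.path(dir, "pairs.csv"),
               manifest = file.path(dir, "manifest.json"))
    write_traces(traces, files["traces"])
    write.csv(layout, files["layout"], row.names = FALSE, quote = FALSE)
    write.csv(pairs, files["pairs"], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

#' Regenerate a synthetic dataset from its manifest
#'
#' Every random quantity in a dataset is reproducible from the manifest
#' alone; regenerating with the same manifest yields byte-identical files.
#'
#' @param manifest a manifest list or a path to `manifest.json`.
#' @param dir optional output directory, as in [generate_dataset()].
#' @return A `"synthetic_dataset"`.
#' @export
dataset_from_manifest <- function(manifest, dir = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  m <- manifest
  generate_dataset(m$rows, m$cols, m$p, m$period, m$duty, m$n_cycles, m$dt,
                   m$alpha, as.list(m$kernel), m$noise_sd, m$seed, dir = dir)
}
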