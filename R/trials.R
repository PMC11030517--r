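# Trial orchestration with a deterministic seed hierarchy: base_seed spawns
# one child seed per (trial, role) for roles lattice / heterogeneity /
# initial conditions.  The children depend only on base_seed and the trial
# index, so sweeping p or q alone does not reshuffle the b_i draws.

make_child_seeds <- function(base_seed, n_trials, roles = 3L) {
  set.seed(base_seed)
  matrix(sample.int(.Machine$integer.max - 1L, n_trials * roles),
         nrow = n_trials, ncol = roles,
         dimnames = list(NULL, c("lattice", "heterogeneity", "init")[seq_len(roles)]))
}

#' Run repeated lattice-network trials
#'
#' Per trial: build a fresh lattice, draw fresh per-node heterogeneity
#' (`tau_i ~ N(T, T/10)`), draw fresh uniform initial conditions — each
#' from deterministic child seeds of `base_seed` — integrate the driven
#' network for `n_periods` drive periods, and score every node with the
#' windowed deviation score (window = `T`).
#'
#' @param topology `"square"` (edge probability `p`) or `"triangular"`
#'   (disruption probability `q`).
#' @param rows,cols lattice dimensions.
#' @param prob the edge probability `p` (square) or disruption probability
#'   `q` (triangular).
#' @param period drive period `T`.
#' @param g cell-cell coupling strength; default `1/(3*period)` (the weak
#'   regime, `g*T = 1/3`).
#' @param g0 drive coupling; default `1/period`.
#' @param n_trials number of independent trials.
#' @param base_seed seed of the trial hierarchy.
#' @param n_periods drive periods per simulation (default 8).
#' @param stride deviation-window stride (default `period/4`).
#' @return A list of class `"trial_set"`: `trials` (data frame with
#'   `trial`, `mean_deviation`, `sd_deviation`, the three child seeds),
#'   `scores` (list of per-node score vectors), `mean_deviation`,
#'   `sd_deviation` (across trial means), and the configuration.
#' @export
run_trials <- function(topology = c("square", "triangular"), rows, cols,
                       prob, period, g = 1 / (3 * period), g0 = 1 / period,
                       n_trials, base_seed, n_periods = 8,
                       stride = period / 4) {
  topology <- match.arg(topology)
  stopifnot(n_trials >= 1)
  seeds <- make_child_seeds(base_seed, n_trials)
  b0 <- b_from_period(period)
  scores <- vector("list", n_trials)
  means <- sds <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    lat <- if (topology == "square") {
      build_square_lattice(rows, cols, p = prob, seed = seeds[k, "lattice"])
    } else {
      build_triangular_lattice(rows, cols, q = prob, seed = seeds[k, "lattice"])
    }
    b_i <- sample_heterogeneity(nrow(lat$nodes), period,
                                seed = seeds[k, "heterogeneity"])
    model <- network_model(lat, b_i, g = g, g0 = g0, b0 = b0)
    sim <- integrate_network(model, n_periods = n_periods,
                             seed = seeds[k, "init"])
    sc <- deviation_score(sim$trace, width = period, stride = stride)
    scores[[k]] <- sc
    means[k] <- mean(sc)
    sds[k] <- sd(sc)
  }
  structure(list(trials = data.frame(trial = seq_len(n_trials),
                                     mean_deviation = means,
                                     sd_deviation = sds,
                                     seed_lattice = seeds[, "lattice"],
                                     seed_heterogeneity = seeds[, "heterogeneity"],
                                     seed_init = seeds[, "init"]),
                 scores = scores,
                 mean_deviation = mean(means), sd_deviation = sd(means),
                 config = list(topology = topology, rows = rows, cols = cols,
                               prob = prob, period = period, g = g, g0 = g0,
                               n_trials = n_trials, base_seed = base_seed,
                               n_periods = n_periods, stride = stride)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<trial_set> %s %dx%d, prob = %g, T = %g: %d trials, mean deviation %.4f (sd %.4f)\n",
              cfg$topology, cfg$rows, cfg$cols, cfg$prob, cfg$period,
              cfg$n_trials, x$mean_deviation, x$sd_deviation))
  invisible(x)
}
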