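# The four model-reproduction experiments and the recording-analysis path.
# Each experiment function is deterministic given its seed, returns a plain
# results table, and optionally writes CSV/JSON outputs.

#' Period sweep of the driven uncoupled pair
#'
#' For each drive period `T`: `n_trials` driven-pair simulations with
#' `g = 0`, intrinsic periods `tau_1, tau_2 ~ N(T, T/10)`, drive coupling
#' `g0 = g0T / T`, random initial phases; deviation scores over a moving
#' window of width `T`. Entrainment improves with `T`, so the mean
#' deviation falls approximately like `T^(-1/2)` (noise integration),
#' quantified by the fitted log-log exponent.
#'
#' Coupling strengths are specified as the dimensionless product with the
#' drive period (`g0T = g0 * T`), the same convention as `g * tau` for the
#' cell-cell coupling: it is the coupling per drive cycle that sets the
#' entrainment regime, and holding `g0T` fixed across the sweep is what
#' produces the clean `T^(-1/2)` decay (a fixed absolute `g0` instead
#' deepens entrainment as `T` grows and collapses the deviation much
#' faster than `T^(-1/2)`).
#'
#' @param periods sweep grid (default `c(5, 10, 20, 50, 100, 200)`).
#' @param g0T dimensionless drive coupling `g0 * T` (default 0.1).
#' @param n_trials trials per period (default 1000).
#' @param n_periods drive periods per simulation (default 8).
#' @param base_seed seed of the trial hierarchy.
#' @return A list of class `"sweep_result"`: `table` (data frame `period`,
#'   `mean_deviation`, `sd_deviation`, `se_deviation`, `n_trials`),
#'   `exponent`, `exponent_stderr` (NA when the grid is too short to fit),
#'   and `config`.
#' @export
exp_period_sweep <- function(periods = c(5, 10, 20, 50, 100, 200), g0T = 0.1,
                             n_trials = 1000, n_periods = 8, base_seed = 1) {
  tab <- data.frame(period = periods, mean_deviation = NA_real_,
                    sd_deviation = NA_real_, se_deviation = NA_real_,
                    n_trials = n_trials)
  for (i in seq_along(periods)) {
    m <- driven_pair_deviations(periods[i], g = 0, g0 = g0T / periods[i],
                                n_trials = n_trials, n_periods = n_periods,
                                base_seed = base_seed)
    tab$mean_deviation[i] <- mean(m)
    tab$sd_deviation[i] <- sd(m)
    tab$se_deviation[i] <- sd(m) / sqrt(n_trials)
  }
  expo <- list(exponent = NA_real_, stderr = NA_real_)
  if (length(periods) >= 4L && all(tab$mean_deviation > 0)) {
    expo <- fit_scaling_exponent(tab$period, tab$mean_deviation)
  }
  structure(list(table = tab, exponent = expo$exponent,
                 exponent_stderr = expo$stderr,
                 config = list(experiment = "period_sweep", periods = periods,
                               g0T = g0T, n_trials = n_trials,
                               n_periods = n_periods, base_seed = base_seed)),
            class = "sweep_result")
}

#' Coupling sweep of the driven pair
#'
#' Fixed drive period `T` (default 20) and drive coupling `g0 = 1/T`;
#' sweeps the gap-junction strength through `g = gT/T` for each value of
#' the dimensionless product `gT`. The mean deviation score rises with
#' coupling: gap-junction-mediated dynamic frustration.
#'
#' @param gT_values dimensionless coupling grid (default
#'   `c(0, 0.5, 1, 2, 3)`).
#' @param period drive period (default 20).
#' @param g0 drive coupling (default `1/period`).
#' @inheritParams exp_period_sweep
#' @return A `"sweep_result"` with column `gT` in the table (no exponent).
#' @export
exp_coupling_sweep <- function(gT_values = c(0, 0.5, 1, 2, 3), period = 20,
                               g0 = 1 / period, n_trials = 1000,
                               n_periods = 8, base_seed = 1) {
  tab <- data.frame(gT = gT_values, g = gT_values / period,
                    mean_deviation = NA_real_, sd_deviation = NA_real_,
                    se_deviation = NA_real_, n_trials = n_trials)
  for (i in seq_along(gT_values)) {
    m <- driven_pair_deviations(period, g = gT_values[i] / period, g0 = g0,
                                n_trials = n_trials, n_periods = n_periods,
                                base_seed = base_seed)
    tab$mean_deviation[i] <- mean(m)
    tab$sd_deviation[i] <- sd(m)
    tab$se_deviation[i] <- sd(m) / sqrt(n_trials)
  }
  structure(list(table = tab, exponent = NA_real_, exponent_stderr = NA_real_,
                 config = list(experiment = "coupling_sweep",
                               gT_values = gT_values, period = period,
                               g0 = g0, n_trials = n_trials,
                               n_periods = n_periods, base_seed = base_seed)),
            class = "sweep_result")
}

# per-trial mean deviation scores of the heterogeneous driven pair.
# Child seeds depend only on (base_seed, trial), so sweeping g or T alone
# keeps the tau_i draws aligned across sweep points.
driven_pair_deviations <- function(period, g, g0, n_trials, n_periods,
                                   base_seed) {
  seeds <- make_child_seeds(base_seed, n_trials, roles = 2L)
  b0 <- b_from_period(period)
  vapply(seq_len(n_trials), function(k) {
    b12 <- sample_heterogeneity(2, period, seed = seeds[k, 1])
    set.seed(seeds[k, 2])
    v0 <- runif(2, 0, 1)
    taus <- c(qif_period(b12), period)
    cfg <- integrator_config(min(taus) / 1000)
    record_every <- max(1L, floor(period / cfg$dt / 200))
    res <- run_core(b12, matrix(c(1L, 2L), 1), g, g0, b0, v0, 0, 0, 1,
                    n_periods * period, cfg$dt, cfg$method, record_every)
    tr <- trace_set(res$times, res$v, period = period)
    mean(deviation_score(tr, width = period))
  }, numeric(1))
}

#' Square-lattice connectivity experiment
#'
#' 18x18 square lattice (default), drive period `T = 20`, 8 drive periods,
#' weak-regime coupling `g = 1/(3T)`, drive `g0 = 1/T`; compares the mean
#' deviation score across edge probabilities `p` (default `{0, 0.75}`). A
#' more connected lattice is less synchronized — dynamic frustration at
#' the network scale.
#'
#' @param p_values edge probabilities (default `c(0, 0.75)`).
#' @param rows,cols lattice size (default 18x18).
#' @param period drive period (default 20).
#' @param g,g0 coupling strengths (defaults `1/(3*period)`, `1/period`).
#' @param n_trials trials per `p` (default 30).
#' @param n_periods drive periods per simulation (default 8).
#' @param base_seed seed (trial k uses the same child seeds at every `p`).
#' @return A list of class `"lattice_result"`: `table` (`p`,
#'   `mean_deviation`, `sd_deviation`, `n_trials`), `trial_sets`, `config`.
#' @export
exp_square_lattice <- function(p_values = c(0, 0.75), rows = 18, cols = 18,
                               period = 20, g = 1 / (3 * period),
                               g0 = 1 / period, n_trials = 30, n_periods = 8,
                               base_seed = 1) {
  sets <- lapply(p_values, function(p)
    run_trials("square", rows, cols, prob = p, period = period, g = g,
               g0 = g0, n_trials = n_trials, base_seed = base_seed,
               n_periods = n_periods))
  tab <- data.frame(p = p_values,
                    mean_deviation = vapply(sets, `[[`, numeric(1), "mean_deviation"),
                    sd_deviation = vapply(sets, `[[`, numeric(1), "sd_deviation"),
                    n_trials = n_trials)
  structure(list(table = tab, trial_sets = sets,
                 config = list(experiment = "square_lattice",
                               p_values = p_values, rows = rows, cols = cols,
                               period = period, g = g, g0 = g0,
                               n_trials = n_trials, n_periods = n_periods,
                               base_seed = base_seed)),
            class = "lattice_result")
}

#' Triangular-lattice disruption experiment
#'
#' 10x10 six-neighbour triangular lattice (default), drive period `T = 20`;
#' compares the mean deviation score across disruption probabilities `q`
#' (default `{0, 0.5}`). Disrupting cells removes their gap-junction edges
#' (they still receive the drive), and the disrupted network is *more*
#' synchronized — the co-culture rescue prediction.
#'
#' @param q_values disruption probabilities (default `c(0, 0.5)`).
#' @param rows,cols lattice size (default 10x10).
#' @param n_trials trials per `q` (default 15).
#' @inheritParams exp_square_lattice
#' @return A `"lattice_result"` with column `q` in the table.
#' @export
exp_triangular_disruption <- function(q_values = c(0, 0.5), rows = 10,
                                      cols = 10, period = 20,
                                      g = 1 / (3 * period), g0 = 1 / period,
                                      n_trials = 15, n_periods = 8,
                                      base_seed = 1) {
  sets <- lapply(q_values, function(q)
    run_trials("triangular", rows, cols, prob = q, period = period, g = g,
               g0 = g0, n_trials = n_trials, base_seed = base_seed,
               n_periods = n_periods))
  tab <- data.frame(q = q_values,
                    mean_deviation = vapply(sets, `[[`, numeric(1), "mean_deviation"),
                    sd_deviation = vapply(sets, `[[`, numeric(1), "sd_deviation"),
                    n_trials = n_trials)
  structure(list(table = tab, trial_sets = sets,
                 config = list(experiment = "triangular_disruption",
                               q_values = q_values, rows = rows, cols = cols,
                               period = period, g = g, g0 = g0,
                               n_trials = n_trials, n_periods = n_periods,
                               base_seed = base_seed)),
            class = "lattice_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<%s>\n", x$config$experiment))
  print(x$table, row.names = FALSE)
  if (!is.na(x$exponent)) {
    cat(sprintf("log-log exponent: %.3f (se %.3f)\n", x$exponent,
                x$exponent_stderr))
  }
  invisible(x)
}

#' @export
print.lattice_result <- function(x, ...) {
  cat(sprintf("<%s>\n", x$config$experiment))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Analyze a recorded (or synthetic) trace file
#'
#' The trace-analysis path: reads a trace CSV (`time` column + one column
#' per node) and a neighbour-pair CSV, computes per-node deviation scores
#' over moving windows of width `period`, per-pair zero-lag
#' cross-correlations, and the sync fraction at the 0.8 threshold; writes
#' per-node and per-pair CSVs plus a JSON summary when `outdir` is given.
#'
#' @param trace_file trace CSV path.
#' @param pair_file neighbour-pair CSV path (or NULL to skip pair metrics).
#' @param period stimulus period (window width), > 0.
#' @param stride window stride (default `period/4`).
#' @param threshold synchrony threshold (default 0.8).
#' @param outdir optional output directory for `node_scores.csv`,
#'   `pair_correlations.csv`, `summary.json`.
#' @return A [sync_report()].
#' @export
analyze_recordings <- function(trace_file, pair_file = NULL, period,
                               stride = period / 4, threshold = 0.8,
                               outdir = NULL) {
  stopifnot(period > 0)
  traces <- read_traces(trace_file, period = period)
  pairs <- if (is.null(pair_file)) NULL else read_pairs(pair_file)
  rep <- sync_report(traces, pairs, width = period, stride = stride,
                     threshold = threshold)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write.csv(rep$node_scores, file.path(outdir, "node_scores.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(rep$pair_correlations)) {
      write.csv(rep$pair_correlations,
                file.path(outdir, "pair_correlations.csv"),
                row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(list(mean_deviation = rep$mean_deviation,
                              sd_deviation = rep$sd_deviation,
                              sync_fraction = rep$sync_fraction,
                              threshold = rep$threshold,
                              period = period, stride = stride,
                              n_nodes = nrow(rep$node_scores),
                              n_pairs = if (is.null(rep$pair_correlations)) 0L
                                        else nrow(rep$pair_correlations)),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

experiment_fields <- list(
  period_sweep = c("periods", "g0T", "n_trials", "n_periods", "base_seed"),
  coupling_sweep = c("gT_values", "period", "g0", "n_trials", "n_periods",
                     "base_seed"),
  square_lattice = c("p_values", "rows", "cols", "period", "g", "g0",
                     "n_trials", "n_periods", "base_seed"),
  triangular_disruption = c("q_values", "rows", "cols", "period", "g", "g0",
                            "n_trials", "n_periods", "base_seed"),
  analyze = c("trace_file", "pair_file", "period", "stride", "threshold",
              "outdir"),
  synth = c("rows", "cols", "p", "period", "duty", "n_cycles", "dt", "alpha",
            "kernel", "noise_sd", "seed", "dir"))

#' Run an experiment from a configuration list
#'
#' Validates the configuration (known experiment id, no unknown keys)
#' before any compute, then dispatches to the matching experiment
#' function. Configurations can be stored as JSON and read back with
#' `jsonlite::read_json(..., simplifyVector = TRUE)`.
#'
#' @param config a list with an `experiment` field (one of `period_sweep`,
#'   `coupling_sweep`, `square_lattice`, `triangular_disruption`,
#'   `analyze`, `synth`) plus that experiment's parameters; omitted
#'   parameters take the documented defaults.
#' @return The dispatched function's result.
#' @export
run_experiment <- function(config) {
  if (is.null(config$experiment) ||
      !config$experiment %in% names(experiment_fields)) {
    stop("`config$experiment` must be one of: ",
         paste(names(experiment_fields), collapse = ", "))
  }
  args <- config[setdiff(names(config), "experiment")]
  unknown <- setdiff(names(args), experiment_fields[[config$experiment]])
  if (length(unknown) > 0L) {
    stop("unknown config keys for ", config$experiment, ": ",
         paste(unknown, collapse = ", "))
  }
  fn <- switch(config$experiment,
               period_sweep = exp_period_sweep,
               coupling_sweep = exp_coupling_sweep,
               square_lattice = exp_square_lattice,
               triangular_disruption = exp_triangular_disruption,
               analyze = analyze_recordings,
               synth = generate_dataset)
  do.call(fn, args)
}
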