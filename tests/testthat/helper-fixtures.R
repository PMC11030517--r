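# shared fixture builders (all data generated in code)

# two anti-phase square waves with values {0,1}: the closed-form deviation
# fixture (population mean 0.5 everywhere, |R - 0.5| = 0.5, score exactly 0.5)
antiphase_square_traces <- function(period = 20, n_cycles = 4, dt = 0.1) {
  times <- seq(0, n_cycles * period - dt, by = dt)
  x <- as.numeric((times %% period) < period / 2)
  trace_set(times, cbind(a = x, b = 1 - x), period = period)
}

# driven-pair deviation for one trial, mirroring the sweep internals but
# assembled from exported pieces only
pair_trial_deviation <- function(period, g, g0, seed, n_periods = 8) {
  set.seed(seed)
  taus <- stats::rnorm(2, period, period / 10)
  taus[taus <= period / 100] <- period
  b12 <- b_from_period(taus)
  v0 <- stats::runif(2, 0, 1)
  cfg <- integrator_config(min(c(taus, period)) / 1000)
  sim <- integrate_driven_pair(b12[1], b12[2], g, b_from_period(period), g0,
                               v0 = v0, t_end = n_periods * period, cfg = cfg)
  mean(deviation_score(sim$trace, width = period))
}
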