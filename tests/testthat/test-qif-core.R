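test_that("analytic period matches the closed form and its quadrature oracle", {
  expect_equal(qif_period(1), pi / 4)
  # independent oracle: the period is the 0 -> 1 transit time of
  # dv/dt = b + v^2, i.e. the integral of 1/(b + v^2) over [0, 1]
  for (b in c(0.25, 1, 4, 10)) {
    osc <- stats::integrate(function(v) 1 / (b + v^2), 0, 1,
                            rel.tol = 1e-12)$value
    expect_equal(qif_period(b), osc, tolerance = 1e-10)
  }
  # strictly decreasing in b, vanishing at large b
  bs <- 10^seq(-3, 3, by = 0.5)
  expect_true(all(diff(qif_period(bs)) < 0))
  expect_lt(qif_period(1e6), 1e-5)
  expect_error(qif_period(0), "b")
  expect_error(qif_period(-1), "b")
})

test_that("period inversion round-trips through the forward formula", {
  expect_equal(b_from_period(pi / 4), 1, tolerance = 1e-10)
  # bisection oracle for tau = 20, frozen: b ~ 0.0055960; the small-b
  # first-order bracket (pi/(2*20))^2 = 0.0061685 lies above it
  b20 <- b_from_period(20)
  expect_equal(b20, 0.005596005, tolerance = 1e-6)
  expect_lt(b20, (pi / 40)^2)
  for (tau in c(0.1, 1, 10, 200, 1000)) {
    expect_lt(abs(qif_period(b_from_period(tau)) - tau) / tau, 1e-10)
  }
})

test_that("regime classification follows the (b, v_reset) bifurcation plane", {
  expect_identical(classify_regime(0.01, 0), "tonic_spiking")
  # fixed points of b + v^2 at +/- 1 for b = -1; reset below the saddle
  expect_identical(classify_regime(-1, -2), "excitable")
  expect_identical(classify_regime(-1, 1.5, v_peak = 2),
                   "reset_above_saddle_spiking")
  expect_identical(classify_regime(0, 0), "on_bifurcation")   # SNHO point
  expect_identical(classify_regime(-1, 1, v_peak = 2), "on_bifurcation")
  expect_error(classify_regime(1, 2, v_peak = 1), "v_reset")
})

test_that("simulated inter-spike intervals match the analytic period", {
  for (b in c(0.1, 1)) {
    tau <- qif_period(b)
    sim <- integrate_qif(b, v0 = 0, t_end = 12 * tau,
                         cfg = integrator_config(tau / 1000))
    isi <- diff(sim$spikes)
    expect_gt(length(isi), 5)
    expect_lt(abs(mean(isi) - tau) / tau, 0.005)
  }
})

test_that("period error converges at least first order in the step", {
  b <- 1
  tau <- qif_period(b)
  isi_err <- function(k, method) {
    sim <- integrate_qif(b, v0 = 0, t_end = 12 * tau,
                         cfg = integrator_config(tau / k, method = method))
    abs(mean(diff(sim$spikes)) - tau) / tau
  }
  # Euler truncation error is visible and shrinks at least linearly
  err <- vapply(c(200, 1000, 5000), isi_err, numeric(1), method = "euler")
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], err[1] / 4)   # 5x refinement, >= first order
  expect_lt(err[3], err[2] / 4)
  # RK4 with interpolated crossings sits far below Euler at the same step
  expect_lt(isi_err(1000, "rk4"), err[2] / 100)
})

test_that("an excitable neuron relaxes to its stable rest without spiking", {
  sim <- integrate_qif(-1, v0 = -2, t_end = 20, v_reset = -2)
  expect_length(sim$spikes, 0)
  v <- sim$trace$values[, 1]
  expect_true(all(diff(v) >= 0))          # monotone approach from below
  expect_equal(v[length(v)], -1, tolerance = 1e-3)
})

test_that("integration is deterministic and rejects an unresolved step", {
  a <- integrate_qif(1, v0 = 0.3, t_end = 5)
  b <- integrate_qif(1, v0 = 0.3, t_end = 5)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$spikes, b$spikes)
  expect_error(integrate_qif(1, v0 = 0, t_end = 5,
                             cfg = integrator_config(qif_period(1) / 50)),
               "tau_min/200")
})

test_that("the symmetric pair preserves its symmetries", {
  b <- b_from_period(5)
  # g = 0, identical initial conditions: trajectories identical forever
  sim <- integrate_pair(b, b, g = 0, v0 = c(0.4, 0.4), t_end = 40)
  expect_identical(sim$trace$values[, 1], sim$trace$values[, 2])
  # coupled, identical initial conditions: symmetry still exact
  sim2 <- integrate_pair(b, b, g = 0.5, v0 = c(0.4, 0.4), t_end = 40)
  expect_identical(sim2$trace$values[, 1], sim2$trace$values[, 2])
})

test_that("strong coupling phase-locks the pair while weak coupling repels it", {
  tau <- 20
  b <- b_from_period(tau)
  for (k in 1:5) {
    set.seed(300 + k)
    v0 <- runif(2, 0, 1)
    strong <- integrate_pair(b, b, g = 3 / tau, v0 = v0, t_end = 50 * tau)
    weak <- integrate_pair(b, b, g = 1 / (3 * tau), v0 = v0, t_end = 50 * tau)
    expect_lt(spike_phase_offset(strong$spikes[[1]], strong$spikes[[2]], tau),
              0.05 * tau)
    expect_gt(spike_phase_offset(weak$spikes[[1]], weak$spikes[[2]], tau),
              0.4 * tau)
  }
})

test_that("the driven pair reduces to the single neuron when uncoupled", {
  # g = g0 = 0, b1 = 1: v1 is a free QIF neuron with period pi/4
  sim <- integrate_driven_pair(1, 1, g = 0, b0 = b_from_period(5), g0 = 0,
                               v0 = c(0, 0.5), t_end = 10 * pi / 4)
  expect_lt(abs(mean(diff(sim$spikes[[1]])) - pi / 4) / (pi / 4), 0.005)
  # fully symmetric driven pair: v1 and v2 coincide, deviation is zero
  b0 <- b_from_period(10)
  sym <- integrate_driven_pair(b0, b0, g = 0, b0 = b0, g0 = 0.2,
                               v0 = c(0.2, 0.2), t_end = 80)
  expect_identical(sym$trace$values[, 1], sym$trace$values[, 2])
  sc <- deviation_score(sym$trace, width = 10)
  expect_equal(as.numeric(sc), c(0, 0))
})

test_that("the drive unit follows its printed period and ignores the neurons", {
  T0 <- 7
  sim <- integrate_driven_pair(b_from_period(6), b_from_period(8), g = 0.1,
                               b0 = b_from_period(T0), g0 = 0.3,
                               v0 = c(0.1, 0.9), t_end = 10 * T0)
  expect_lt(abs(mean(diff(sim$drive_spikes)) - T0) / T0, 0.005)
})
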