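# Integrators: thin wrappers over the compiled fixed-step RK4/Euler core
# with interpolated reset-crossing detection.  All of them share the model
#
#   dv_i/dt = b_i + v_i^2 + g * sum_{j~i} (v_j - v_i) + g0 * (u - v_i)
#   du/dt   = b0 + u^2,   u resets 1 -> 0 (so its period is the analytic
#                         transit time b0^{-1/2} atan(b0^{-1/2}))
#
# The drive u is autonomous: it forces the network but is not influenced by
# it.  A resetting unit's voltage is discontinuous; partners see the
# post-reset value from the crossing step onward (diffusive coupling only —
# no synaptic pulse is transmitted).

run_core <- function(b, edges, g, g0, b0, v0, u0, v_reset, v_peak,
                     t_end, dt, method, record_every = 1L) {
  stopifnot(t_end > 0, dt > 0)
  check_dt(dt, c(b[b > 0], if (b0 > 0) b0))
  n_steps <- max(1L, as.integer(round(t_end / dt)))
  if (is.null(edges) || nrow(edges) == 0L) {
    ei <- integer(0); ej <- integer(0)
  } else {
    ei <- as.integer(edges[, 1]) - 1L
    ej <- as.integer(edges[, 2]) - 1L
  }
  res <- .qif_integrate_cpp(as.numeric(b), ei, ej, g, g0, b0,
                            v_reset, v_peak, as.numeric(v0), u0, dt,
                            n_steps, as.integer(record_every),
                            identical(method, "rk4"))
  colnames(res$v) <- paste0("n", seq_along(b))
  res
}

#' Integrate a single QIF neuron
#'
#' Fixed-step integration of `dv/dt = b + v^2` with reset: when a step
#' carries `v` across `v_peak`, the crossing time is located by linear
#' interpolation within the step, recorded as a spike, and the trajectory
#' restarts from `v_reset`.
#'
#' @param b drive parameter. Positive values spike tonically with the
#'   analytic period [qif_period()]; negative values are excitable or
#'   spiking depending on `v_reset` (see [classify_regime()]).
#' @param v0 initial voltage in `[v_reset, v_peak)`.
#' @param t_end integration horizon.
#' @param v_reset,v_peak reset value and spike threshold.
#' @param cfg an [integrator_config()]; default step is `qif_period(b)/1000`
#'   for spiking `b`, else `t_end/10000`.
#' @return A list with `trace` (a [trace_set()]) and `spikes` (ordered
#'   reset-crossing times).
#' @examples
#' sim <- integrate_qif(1, v0 = 0, t_end = 10 * pi / 4)
#' mean(diff(sim$spikes))  # ~ pi/4
#' @export
integrate_qif <- function(b, v0, t_end, v_reset = 0, v_peak = 1, cfg = NULL) {
  stopifnot(length(b) == 1L, v_reset < v_peak, v0 >= v_reset, v0 < v_peak)
  if (is.null(cfg)) {
    dt <- if (b > 0) qif_period(b) / 1000 else t_end / 10000
    cfg <- integrator_config(dt)
  }
  res <- run_core(b, NULL, 0, 0, 0, v0, 0, v_reset, v_peak,
                  t_end, cfg$dt, cfg$method)
  list(trace = trace_set(res$times, res$v), spikes = res$spikes[[1]])
}

#' Integrate two gap-junction-coupled QIF neurons
#'
#' The symmetric diffusively coupled pair
#' `dv1/dt = b1 + v1^2 + g (v2 - v1)`, `dv2/dt = b2 + v2^2 + g (v1 - v2)`,
#' each neuron resetting independently at `v_peak`. Near the SNHO point,
#' weak coupling (`g` below roughly `1/tau`) drives the pair toward
#' anti-phase spiking while strong coupling (`g` above `1/tau`)
#' synchronizes it.
#'
#' @param b1,b2 per-neuron drive parameters (a common `b` is the undriven
#'   textbook case).
#' @param g gap-junction coupling strength, >= 0.
#' @param v0 length-2 vector of initial voltages.
#' @inheritParams integrate_qif
#' @return A list with `trace` (two-column [trace_set()]) and `spikes`
#'   (list of two spike-time vectors).
#' @export
integrate_pair <- function(b1, b2, g, v0, t_end, v_reset = 0, v_peak = 1,
                           cfg = NULL) {
  stopifnot(g >= 0, length(v0) == 2L, v_reset < v_peak)
  b <- c(b1, b2)
  if (is.null(cfg)) {
    dt <- if (any(b > 0)) min(qif_period(b[b > 0])) / 1000 else t_end / 10000
    cfg <- integrator_config(dt)
  }
  res <- run_core(b, matrix(c(1L, 2L), 1), g, 0, 0, v0, 0,
                  v_reset, v_peak, t_end, cfg$dt, cfg$method)
  list(trace = trace_set(res$times, res$v), spikes = res$spikes)
}

#' Integrate a driven pair of coupled QIF neurons
#'
#' Adds a periodic forcing unit `u` (itself a QIF unit on thresholds
#' `(0, 1)`, so its period is `T = b0^{-1/2} atan(b0^{-1/2})`) that drives
#' both neurons diffusively with strength `g0`:
#' `dv_i/dt = b_i + v_i^2 + g (v_j - v_i) + g0 (u - v_i)`. The drive is
#' autonomous — it is not influenced by the neurons.
#'
#' @param b0 drive-unit parameter; set it via [b_from_period()] to obtain a
#'   prescribed forcing period.
#' @param g0 drive-to-neuron coupling strength, >= 0.
#' @param u0 initial drive state in `[0, 1)`.
#' @inheritParams integrate_pair
#' @return A list with `trace` (neurons), `drive` ([trace_set()] of `u`),
#'   `spikes` (list of two), and `drive_spikes`.
#' @export
integrate_driven_pair <- function(b1, b2, g, b0, g0, v0, u0 = 0, t_end,
                                  v_reset = 0, v_peak = 1, cfg = NULL) {
  stopifnot(g >= 0, g0 >= 0, b0 > 0, length(v0) == 2L, u0 >= 0, u0 < 1)
  b <- c(b1, b2)
  if (is.null(cfg)) {
    taus <- c(qif_period(b[b > 0]), qif_period(b0))
    cfg <- integrator_config(min(taus) / 1000)
  }
  res <- run_core(b, matrix(c(1L, 2L), 1), g, g0, b0, v0, u0,
                  v_reset, v_peak, t_end, cfg$dt, cfg$method)
  list(trace = trace_set(res$times, res$v),
       drive = trace_set(res$times, matrix(res$u, dimnames = list(NULL, "u"))),
       spikes = res$spikes, drive_spikes = res$u_spikes)
}
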