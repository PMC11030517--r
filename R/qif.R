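#' Analytic period of the quadratic integrate-and-fire neuron
#'
#' For the QIF model `dv/dt = b + v^2` with reset thresholds
#' `v_reset = 0`, `v_peak = 1`, the transit time from 0 to 1 — and hence the
#' tonic spiking period for `b > 0` — has the closed form
#' \deqn{\tau = b^{-1/2} \tan^{-1}(b^{-1/2}).}
#'
#' The period diverges as `b` approaches the saddle-node at `b = 0` from
#' above (like \eqn{\pi / (2\sqrt{b})}) and shrinks to zero as `b` grows
#' (like `1/b`); it is strictly decreasing in `b`.
#'
#' @param b drive parameter(s), strictly positive (units time^-2).
#' @return Spiking period(s), same length as `b`.
#' @seealso [b_from_period()] for the inverse map.
#' @examples
#' qif_period(1)        # pi / 4
#' qif_period(c(0.01, 0.1, 1, 10))
#' @export
qif_period <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b)) || any(b <= 0)) {
    stop("`b` must be finite and > 0 (the closed-form period exists only in the tonic spiking regime)")
  }
  s <- sqrt(b)
  atan(1 / s) / s
}

#' Drive parameter giving a prescribed spiking period
#'
#' Inverts the analytic period map [qif_period()] by bracketed root finding
#' on the strictly monotone forward formula. Needed because cell-to-cell
#' heterogeneity is specified on periods (Gaussian with mean `T` and sd
#' `T/10`), not on `b` directly.
#'
#' @param tau target period(s), strictly positive.
#' @param tol relative tolerance of the root find; the round trip
#'   `qif_period(b_from_period(tau))` agrees with `tau` to better than 1e-10
#'   relative error at the default.
#' @return Drive parameter(s) `b` with `qif_period(b) == tau`.
#' @examples
#' b_from_period(pi / 4)  # 1
#' qif_period(b_from_period(20))
#' @export
b_from_period <- function(tau, tol = 1e-13) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be finite and > 0")
  }
  vapply(tau, function(t1) {
    # tau(b) < (pi/2)/sqrt(b), so b = (pi/(2*tau))^2 overshoots the period
    # from below: f(hi) < 0.  Walk lo downward until f(lo) > 0.
    hi <- (pi / (2 * t1))^2 + 1 / t1
    lo <- hi / 2
    while (qif_period(lo) < t1) lo <- lo / 2
    uniroot(function(b) qif_period(b) - t1,
            lower = lo, upper = hi, tol = tol * hi)$root
  }, numeric(1))
}

#' Classify the dynamical regime of a QIF neuron
#'
#' The `(b, v_reset)` plane of the QIF model carries a saddle-node
#' bifurcation (at `b = 0`) and a saddle homoclinic orbit bifurcation (at
#' `v_reset = +sqrt(-b)` for `b < 0`); they intersect at the codimension-2
#' saddle-node homoclinic orbit (SNHO) point `(0, 0)`. Proximity to the SNHO
#' point is what drives anti-phase locking under diffusive coupling.
#'
#' * `b > 0`: no fixed points — tonic spiking (`"tonic_spiking"`).
#' * `b < 0`: fixed points at `-sqrt(-b)` (stable) and `+sqrt(-b)` (saddle).
#'   A reset below the saddle traps the trajectory at rest
#'   (`"excitable"`); a reset above it re-injects the trajectory on the
#'   escaping branch each cycle (`"reset_above_saddle_spiking"`).
#' * On either bifurcation curve (within `tol`) the regime is flagged
#'   explicitly as `"on_bifurcation"` rather than silently assigned.
#'
#' @param b drive parameter.
#' @param v_reset post-spike reset voltage; must be below `v_peak`.
#' @param v_peak spike threshold (default 1).
#' @param tol half-width of the band treated as exactly on a bifurcation.
#' @return A character scalar, one of `"tonic_spiking"`, `"excitable"`,
#'   `"reset_above_saddle_spiking"`, `"on_bifurcation"`.
#' @examples
#' classify_regime(0.01, 0)  # tonic spiking near the SNHO point
#' classify_regime(-1, -2)   # excitable
#' classify_regime(0, 0)     # the SNHO bifurcation itself
#' @export
classify_regime <- function(b, v_reset, v_peak = 1, tol = 1e-12) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(v_reset), length(v_reset) == 1L, is.finite(v_reset))
  if (v_reset >= v_peak) stop("`v_reset` must be below `v_peak`")
  if (abs(b) <= tol) return("on_bifurcation")
  if (b > 0) return("tonic_spiking")
  saddle <- sqrt(-b)
  if (abs(v_reset - saddle) <= tol) return("on_bifurcation")
  if (v_reset < saddle) "excitable" else "reset_above_saddle_spiking"
}

#' Integrator configuration
#'
#' Fixed-step configuration shared by all integrators. The step must resolve
#' the fastest unit: `dt` may not exceed 1/200 of the smallest analytic
#' period among the spiking units it is used with (the wrappers check this;
#' defaults use 1/1000).
#'
#' @param dt step size (model time), > 0.
#' @param method `"rk4"` (default) or `"euler"`.
#' @param seed optional integer seed used by callers that draw random
#'   initial conditions.
#' @return A list of class `"integrator_config"`.
#' @export
integrator_config <- function(dt, method = c("rk4", "euler"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  structure(list(dt = dt, method = method, seed = seed),
            class = "integrator_config")
}

# dt must resolve the fastest spiking unit: dt <= tau_min / 200.
# b_spiking: drive parameters of units with b > 0 (non-spiking units put no
# constraint on the step).
check_dt <- function(dt, b_spiking) {
  if (length(b_spiking) == 0L) return(invisible(dt))
  tau_min <- min(qif_period(b_spiking))
  if (dt > tau_min / 200) {
    stop(sprintf("dt = %g exceeds tau_min/200 = %g; reduce the step",
                 dt, tau_min / 200))
  }
  invisible(dt)
}
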