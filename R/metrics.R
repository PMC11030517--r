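# Synchrony statistics, applied identically to simulated voltage traces and
# calcium-recording-style response traces.

#' Linearly rescale one window of samples to [0, 1]
#'
#' The affine map `(x - min) / (max - min)`. A constant segment cannot be
#' rescaled; it is returned as all zeros and flagged degenerate (attribute
#' `"degenerate"`), never an error — degenerate windows are skipped by the
#' deviation score.
#'
#' @param segment numeric vector of length >= 2.
#' @return The rescaled vector with a logical `"degenerate"` attribute.
#' @export
normalize_window <- function(segment) {
  stopifnot(is.numeric(segment), length(segment) >= 2L)
  rng <- range(segment)
  if (rng[1] == rng[2]) {
    return(structure(rep(0, length(segment)), degenerate = TRUE))
  }
  structure((segment - rng[1]) / (rng[2] - rng[1]), degenerate = FALSE)
}

# trapezoidal integral of y on a uniform grid with spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}

#' Windowed deviation score from the population mean
#'
#' For each moving window of width equal to the stimulus period `T`, every
#' node's segment is linearly rescaled to `[0, 1]`
#' ([normalize_window()]), the population-average normalized curve is
#' formed, and node `i` scores the time-averaged absolute area between its
#' curve and the population average:
#' \deqn{s_i = \frac{1}{T}\int_{window} |R_{i,N}(t) - \langle R_{N}(t)\rangle|\,dt}
#' (trapezoidal quadrature). The per-node score is the mean over windows,
#' excluding windows where that node's segment was degenerate (constant).
#' The score is dimensionless, lies in `[0, 1]`, and approaches zero when
#' all nodes synchronize perfectly; window normalization makes it invariant
#' to per-node affine rescaling of the raw traces.
#'
#' @param traces a [trace_set()] or a numeric matrix (rows = time points,
#'   columns = nodes; at least two nodes).
#' @param width window width in time units — use the stimulus period.
#' @param stride hop between window starts (default `width/4`).
#' @param dt grid spacing; taken from `traces` when it is a trace set.
#' @return Numeric vector of per-node scores (named by node), with
#'   attributes `"window_scores"` (windows x nodes matrix, `NA` where
#'   degenerate) and `"n_degenerate"`.
#' @examples
#' t <- seq(0, 40, by = 0.1)
#' x <- as.numeric(t %% 20 < 10)           # square wave, period 20
#' deviation_score(cbind(a = x, b = 1 - x), width = 20, dt = 0.1)  # 0.5, 0.5
#' @export
deviation_score <- function(traces, width, stride = width / 4, dt = NULL) {
  vals <- as_trace_matrix(traces)
  if (ncol(vals) < 2L) {
    stop("deviation score needs at least 2 nodes (population average is undefined otherwise)")
  }
  if (is.null(dt)) {
    if (!inherits(traces, "trace_set")) {
      stop("`dt` must be given when `traces` is a bare matrix")
    }
    dt <- traces$times[2] - traces$times[1]
  }
  stopifnot(width > 0, stride > 0, stride <= width + 1e-12)
  L <- nrow(vals)
  n_w <- as.integer(round(width / dt)) + 1L  # samples spanning `width`
  if (n_w < 2L) stop("window width must span at least 2 samples")
  if (n_w > L) stop("window width exceeds the record length")
  stride_n <- max(1L, as.integer(round(stride / dt)))
  starts <- seq.int(1L, L - n_w + 1L, by = stride_n)
  span <- (n_w - 1L) * dt

  win_scores <- matrix(NA_real_, length(starts), ncol(vals))
  n_degenerate <- 0L
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + n_w - 1L)
    seg <- vals[idx, , drop = FALSE]
    rng_min <- apply(seg, 2, min)
    rng_max <- apply(seg, 2, max)
    degen <- rng_max == rng_min
    n_degenerate <- n_degenerate + sum(degen)
    norm <- sweep(seg, 2, rng_min, "-")
    scale <- ifelse(degen, 1, rng_max - rng_min)
    norm <- sweep(norm, 2, scale, "/")
    norm[, degen] <- 0
    pop_mean <- rowMeans(norm)
    dev <- abs(norm - pop_mean)
    sc <- apply(dev, 2, trapz_uniform, dt = dt) / span
    sc[degen] <- NA_real_
    win_scores[w, ] <- sc
  }
  node_scores <- colMeans(win_scores, na.rm = TRUE)
  names(node_scores) <- colnames(vals)
  structure(node_scores, window_scores = win_scores,
            n_degenerate = n_degenerate)
}

#' Zero-lag cross-correlation between two response series
#'
#' Pearson correlation of the full records at zero lag — the bounded
#' coefficient on which the 0.8 synchrony threshold operates.
#'
#' @param x,y equal-length numeric series, neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation is undefined for a constant series")
  }
  cor(x, y)
}

#' Fraction of well-synchronized neighbour pairs
#'
#' The fraction of pairs whose cross-correlation coefficient is strictly
#' greater than the threshold (pairs at exactly the threshold do not
#' count).
#'
#' @param correlations per-pair coefficients; at least one pair.
#' @param threshold synchrony cut-off (default 0.8).
#' @return `P_sync` in `[0, 1]`.
#' @export
sync_fraction <- function(correlations, threshold = 0.8) {
  if (length(correlations) == 0L) stop("no pairs: P_sync is undefined")
  mean(correlations > threshold)
}

#' Asymptotic spike-phase offset between two spike trains
#'
#' Quantifies in-phase vs anti-phase locking: over the last third of the
#' record (the first two thirds are discarded as transient), each spike of
#' the first train is matched to the nearest spike of the second, the time
#' differences are folded circularly into `[0, period/2]`, and their mean is
#' returned. 0 means in-phase lock; `period/2` means anti-phase.
#'
#' @param sa,sb spike-time vectors; each needs at least 5 spikes after the
#'   transient cut.
#' @param period locking period used for the circular fold.
#' @return Offset in `[0, period/2]`.
#' @export
spike_phase_offset <- function(sa, sb, period) {
  stopifnot(period > 0)
  t_end <- max(c(sa, sb))
  cut <- 2 / 3 * t_end
  a <- sa[sa > cut]
  if (length(a) < 5L || length(sb[sb > cut]) < 5L) {
    stop("need at least 5 spikes per train after the transient cut")
  }
  offs <- vapply(a, function(t1) {
    d <- min(abs(sb - t1)) %% period
    min(d, period - d)
  }, numeric(1))
  mean(offs)
}

#' Fit a power-law scaling exponent on log-log axes
#'
#' Least-squares slope of `log(score)` against `log(T)`, used to compare
#' the decay of the deviation score with the stimulus period against the
#' `T^(-1/2)` noise-integration prediction.
#'
#' @param periods >= 4 period values.
#' @param scores matching mean deviation scores, all > 0.
#' @return A list with `exponent`, `stderr`, and the `fit` (an `lm`).
#' @export
fit_scaling_exponent <- function(periods, scores) {
  stopifnot(length(periods) == length(scores))
  if (length(periods) < 4L) stop("need at least 4 period values to fit a slope")
  if (any(scores <= 0)) stop("scores must be positive for a log-log fit")
  fit <- lm(log(scores) ~ log(periods))
  # summary() warns on exact power laws (perfect fit); the slope is still valid
  sm <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(coef(fit)[2]), stderr = unname(sm[2, 2]), fit = fit)
}

#' Full synchrony report for a trace set and neighbour-pair list
#'
#' Runs the deviation score, the per-pair zero-lag cross-correlation, and
#' the sync fraction in one pass — the analysis applied to both recordings
#' and simulations.
#'
#' @param traces a [trace_set()].
#' @param pairs data frame with columns `node_i`, `node_j` (node ids
#'   matching the trace columns) and optionally `provenance`.
#' @param width deviation-score window width (stimulus period); defaults to
#'   `traces$period`.
#' @param stride window stride (default `width/4`).
#' @param threshold synchrony threshold for `P_sync` (default 0.8).
#' @return A list of class `"sync_report"`: `node_scores` (data frame),
#'   `pair_correlations` (data frame), `sync_fraction`, `threshold`,
#'   `mean_deviation`, `sd_deviation`.
#' @export
sync_report <- function(traces, pairs, width = NULL, stride = NULL,
                        threshold = 0.8) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(width)) width <- traces$period
  if (is.null(width)) stop("no window width: give `width` or a trace-set period")
  if (is.null(stride)) stride <- width / 4
  scores <- deviation_score(traces, width = width, stride = stride)
  ids <- colnames(traces$values)
  corr <- NULL
  psync <- NA_real_
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    bad <- setdiff(c(pairs$node_i, pairs$node_j), ids)
    if (length(bad) > 0L) {
      stop("pair list references unknown node ids: ", paste(bad, collapse = ", "))
    }
    r <- mapply(function(i, j) cross_correlation(traces$values[, i],
                                                 traces$values[, j]),
                as.character(pairs$node_i), as.character(pairs$node_j))
    corr <- data.frame(node_i = pairs$node_i, node_j = pairs$node_j,
                       correlation = as.numeric(r))
    if (!is.null(pairs$provenance)) corr$provenance <- pairs$provenance
    psync <- sync_fraction(corr$correlation, threshold)
  }
  structure(list(node_scores = data.frame(node_id = ids,
                                          deviation = as.numeric(scores)),
                 pair_correlations = corr,
                 sync_fraction = psync, threshold = threshold,
                 mean_deviation = mean(scores),
                 sd_deviation = sd(scores)),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report> %d nodes, mean deviation %.4f (sd %.4f)",
              nrow(x$node_scores), x$mean_deviation, x$sd_deviation))
  if (!is.null(x$pair_correlations)) {
    cat(sprintf("; %d pairs, P_sync(>%g) = %.3f",
                nrow(x$pair_correlations), x$threshold, x$sync_fraction))
  }
  cat("\n")
  invisible(x)
}
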