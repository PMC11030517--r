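test_that("window normalization maps affinely onto [0,1] and flags constants", {
  expect_equal(as.numeric(normalize_window(c(2, 4, 6))), c(0, 0.5, 1))
  set.seed(1)
  x <- normalize_window(rnorm(50))
  expect_equal(range(x), c(0, 1))
  expect_false(attr(x, "degenerate"))
  flat <- normalize_window(c(5, 5, 5))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_true(attr(flat, "degenerate"))
})

test_that("deviation score golden values hold", {
  # identical nodes -> exactly zero
  t <- seq(0, 40, by = 0.1)
  y <- sin(2 * pi * t / 20) + 2
  expect_equal(as.numeric(deviation_score(cbind(a = y, b = y, c = y),
                                      width = 20, dt = 0.1)),
               c(0, 0, 0))
  # anti-phase 50%-duty square waves -> exactly 0.5 for both nodes
  tr <- antiphase_square_traces()
  expect_equal(as.numeric(deviation_score(tr, width = 20)), c(0.5, 0.5))
  # invariant to per-node positive affine rescaling of the raw traces
  set.seed(7)
  raw <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  scaled <- sweep(sweep(raw, 2, c(2, 0.5, 7), "*"), 2, c(-1, 3, 100), "+")
  s1 <- deviation_score(raw, width = 5, dt = 0.1)
  s2 <- deviation_score(scaled, width = 5, dt = 0.1)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("deviation score is bounded, permutation-equivariant, and window-counted", {
  set.seed(11)
  vals <- matrix(runif(1000), 250, 4, dimnames = list(NULL, paste0("n", 1:4)))
  sc <- deviation_score(vals, width = 4, stride = 1, dt = 0.1)
  ws <- attr(sc, "window_scores")
  expect_true(all(ws >= 0 & ws <= 1, na.rm = TRUE))
  # windows: n_w = 41 samples, stride 10 -> floor((250 - 41)/10) + 1 = 21
  expect_equal(nrow(ws), 21)
  # permuting node columns permutes the scores identically
  perm <- c(3, 1, 4, 2)
  sc_p <- deviation_score(vals[, perm], width = 4, stride = 1, dt = 0.1)
  expect_equal(as.numeric(sc_p), as.numeric(sc)[perm])
  # a single window: grand mean of window scores equals mean node score
  one <- deviation_score(vals[1:41, ], width = 4, stride = 4, dt = 0.1)
  expect_equal(mean(attr(one, "window_scores")), mean(one))
  expect_error(deviation_score(vals[, 1, drop = FALSE], width = 4, dt = 0.1),
               "2 nodes")
})

test_that("cross-correlation matches its Pearson fixtures", {
  t <- seq(0, 10 - 0.001, by = 0.001)
  x <- sin(2 * pi * t)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  # quarter-period shift over whole periods: orthogonal
  y <- sin(2 * pi * t + pi / 2)
  expect_lt(abs(cross_correlation(x, y)), 1e-10)
  expect_error(cross_correlation(rep(1, 10), 1:10), "constant")
})

test_that("sync fraction counts strictly above the threshold", {
  expect_equal(sync_fraction(rep(1, 5)), 1)
  expect_equal(sync_fraction(c(0.9, 0.7)), 0.5)
  expect_equal(sync_fraction(c(0.8, 0.9)), 0.5)  # exactly 0.8 not counted
  expect_error(sync_fraction(numeric(0)), "undefined")
})

test_that("spike-phase offsets fold circularly into [0, period/2]", {
  s <- seq(5, 200, by = 10)
  expect_equal(spike_phase_offset(s, s, 10), 0)
  expect_equal(spike_phase_offset(s, s + 5, 10), 5)
  expect_equal(spike_phase_offset(s, s + 9, 10), 1)  # 0.9 period folds to 0.1
  expect_error(spike_phase_offset(s[1:3], s[1:3] + 1, 10), "5 spikes")
})

test_that("scaling-exponent fits recover exact power laws", {
  Ts <- c(40, 80, 120, 160, 200)
  f <- fit_scaling_exponent(Ts, 3 * Ts^(-0.5))
  expect_equal(f$exponent, -0.5, tolerance = 1e-10)
  expect_lt(f$stderr, 1e-10)
  expect_equal(fit_scaling_exponent(Ts, rep(2, 5))$exponent, 0)
  expect_error(fit_scaling_exponent(Ts, c(1, 1, 0, 1, 1)), "positive")
  expect_error(fit_scaling_exponent(Ts[1:3], c(1, 2, 3)), "4 period")
})

test_that("sync_report assembles all three statistics coherently", {
  tr <- antiphase_square_traces()
  pairs <- data.frame(node_i = "a", node_j = "b")
  rep <- sync_report(tr, pairs)
  expect_equal(rep$node_scores$deviation, c(0.5, 0.5))
  expect_equal(rep$pair_correlations$correlation, -1)
  expect_equal(rep$sync_fraction, 0)
  expect_error(sync_report(tr, data.frame(node_i = "a", node_j = "zz")),
               "unknown node")
})
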