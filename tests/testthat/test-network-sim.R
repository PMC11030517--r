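test_that("square-lattice edge construction matches the nearest-neighbour count", {
  expect_equal(nrow(build_square_lattice(18, 18, p = 0, seed = 1)$edges), 0)
  full <- build_square_lattice(18, 18, p = 1, seed = 1)
  expect_equal(nrow(full$edges), 2 * 18 * 18 - 18 - 18)  # 612
  # no self-loops, each edge listed once with i < j
  expect_true(all(full$edges[, 1] < full$edges[, 2]))
  expect_equal(anyDuplicated(full$edges), 0)
  # degrees bounded by 4
  deg <- tabulate(c(full$edges), nbins = 18 * 18)
  expect_true(all(deg <= 4))
})

test_that("edge inclusion is Bernoulli(p) across seeds", {
  counts <- vapply(1:200, function(s)
    nrow(build_square_lattice(18, 18, p = 0.75, seed = s)$edges), numeric(1))
  m <- 612 * 0.75
  se <- sqrt(612 * 0.75 * 0.25) / sqrt(200)
  expect_lt(abs(mean(counts) - m), 3 * se)
})

test_that("triangular lattice has six-neighbour interiors and exact disruption semantics", {
  full <- build_triangular_lattice(10, 10, q = 0, seed = 1)
  deg <- tabulate(c(full$edges), nbins = 100)
  interior <- with(full$nodes, row > 1 & row < 10 & col > 1 & col < 10)
  expect_true(all(deg[interior] == 6))
  expect_true(all(deg <= 6))
  expect_equal(nrow(build_triangular_lattice(10, 10, q = 1, seed = 1)$edges), 0)

  dis <- build_triangular_lattice(10, 10, q = 0.5, seed = 7)
  # surviving edges are exactly the full-lattice edges with both endpoints
  # undisrupted; disrupted nodes remain in the node table
  bad <- dis$nodes$node_id[dis$nodes$disrupted]
  survivors <- full$edges[!(full$edges[, 1] %in% bad | full$edges[, 2] %in% bad), ]
  expect_equal(dis$edges, survivors)
  expect_equal(nrow(dis$nodes), 100)
})

test_that("heterogeneity sampling recovers the target period distribution", {
  T0 <- 20
  b <- sample_heterogeneity(1e4, T0, seed = 99)
  taus <- qif_period(b)
  expect_lt(abs(mean(taus) - T0), 3 * (T0 / 10) / sqrt(1e4))
  expect_lt(abs(sd(taus) - T0 / 10) / (T0 / 10), 0.05)
  expect_identical(b, sample_heterogeneity(1e4, T0, seed = 99))
})

test_that("diffusive coupling conserves total charge", {
  lat <- build_square_lattice(5, 5, p = 1, seed = 1)
  set.seed(2)
  v <- runif(25)
  field <- frustranet:::.qif_coupling_field_cpp(
    v, lat$edges[, 1] - 1L, lat$edges[, 2] - 1L, 0.3)
  expect_equal(sum(field), 0, tolerance = 1e-12)
})

test_that("a two-node network reproduces the driven pair exactly", {
  period <- 10
  b0 <- b_from_period(period)
  b12 <- b_from_period(c(9, 11))
  lat <- build_square_lattice(2, 2, p = 0, seed = 1)
  lat$edges <- matrix(c(1L, 2L), 1)  # single bridged pair; nodes 3,4 isolated
  bvals <- c(b12, b_from_period(c(10, 10)))
  model <- network_model(lat, bvals, g = 0.05, g0 = 1 / period, b0 = b0)
  cfg <- integrator_config(min(qif_period(bvals), period) / 1000)
  v0 <- c(0.1, 0.6, 0.3, 0.8)
  net <- integrate_network(model, n_periods = 3, v0 = v0, cfg = cfg,
                           record_every = 1)
  pair <- integrate_driven_pair(b12[1], b12[2], g = 0.05, b0 = b0,
                                g0 = 1 / period, v0 = v0[1:2],
                                t_end = 3 * period, cfg = cfg)
  expect_identical(net$trace$values[, 1:2], pair$trace$values)
  expect_identical(net$spikes[[1]], pair$spikes[[1]])
  expect_identical(net$spikes[[2]], pair$spikes[[2]])
})

test_that("an uncoupled network decouples into independent driven neurons", {
  period <- 10
  b0 <- b_from_period(period)
  lat <- build_square_lattice(2, 2, p = 0, seed = 3)
  bvals <- sample_heterogeneity(4, period, seed = 4)
  model <- network_model(lat, bvals, g = 0.7, g0 = 1 / period, b0 = b0)
  cfg <- integrator_config(min(qif_period(bvals), period) / 1000)
  v0 <- c(0.15, 0.35, 0.55, 0.75)
  net <- integrate_network(model, n_periods = 3, v0 = v0, cfg = cfg,
                           record_every = 1)
  for (i in 1:4) {
    solo <- integrate_driven_pair(bvals[i], bvals[i], g = 0, b0 = b0,
                                  g0 = 1 / period, v0 = rep(v0[i], 2),
                                  t_end = 3 * period, cfg = cfg)
    expect_identical(unname(net$trace$values[, i]),
                     unname(solo$trace$values[, 1]))
  }
})

test_that("trial runs are reproducible and more connectivity raises deviation", {
  a <- run_trials("square", 4, 4, prob = 0.5, period = 10, n_trials = 2,
                  base_seed = 21)
  b <- run_trials("square", 4, 4, prob = 0.5, period = 10, n_trials = 2,
                  base_seed = 21)
  expect_identical(a$trials, b$trials)
  expect_true(all(unlist(a$scores) >= 0 & unlist(a$scores) <= 1))

  # direction of the connectivity effect on a small lattice
  lo <- run_trials("square", 8, 8, prob = 0, period = 20, n_trials = 5,
                   base_seed = 33)
  hi <- run_trials("square", 8, 8, prob = 0.75, period = 20, n_trials = 5,
                   base_seed = 33)
  expect_gt(hi$mean_deviation, lo$mean_deviation)
})
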