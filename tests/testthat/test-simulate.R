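test_that("Lorenz simulation is seeded, bounded, and synchronizes when coupled", {
  cfg <- lorenz_config(g = 0, transient = 2000, length = 400, seed = 5)
  a <- simulate_coupled_lorenz(cfg)
  b <- simulate_coupled_lorenz(cfg)
  expect_identical(a, b)               # bitwise reproducible
  expect_identical(nrow(a), 400L)
  # uncoupled: both stay within the classic attractor extent
  expect_true(all(abs(c(a$x1, a$y1)) < 25))
  # different seeds explore different trajectories
  expect_false(identical(
    a$x1, simulate_coupled_lorenz(lorenz_config(g = 0, transient = 2000,
                                                length = 400, seed = 6))$x1))

  sync <- lorenz_pair(5, seed = 8)  # full transient protocol
  # complete synchronization up to the solver's local error scale
  expect_lt(max(abs(sync$x1 - sync$y1)), 1e-3)
})

test_that("detection rates behave on closed-form pairs", {
  set.seed(79)
  u <- as.numeric(stats::filter(rnorm(400), 0.9, method = "recursive"))
  expect_equal(op_detection_rate(u, u, 3, 5), 1)
  expect_equal(cor_detection_rate(u, 2 * u + 3, 2, 30), 1)  # affine copy
  v <- rev(u)
  expect_lte(op_detection_rate(u, v, 4, 3), 1)
  # constant channel: every window is degenerate
  expect_warning(r0 <- cor_detection_rate(u, rep(1, 400), 2, 30), "zero-variance")
  expect_equal(r0, 0)
  expect_error(cor_detection_rate(u[1:20], u[1:20], 2, 30), "shorter than one window")
})

test_that("synchronized pairs match symbols while independent pairs rarely do", {
  sync <- lorenz_pair(5, seed = 8)
  expect_gt(op_detection_rate(sync$x1, sync$y1, 2, 30), 0.94)
  indep <- lorenz_pair(0, seed = 8, transient = 2000, length = 400)
  r2 <- op_detection_rate(indep$x1, indep$y1, 2, 30)
  r6 <- op_detection_rate(indep$x1, indep$y1, 6, 30)
  expect_lt(r6, r2)  # over-embedding suppresses chance matches
  expect_lt(r6, 0.1)
})

test_that("the benchmark grid has the full design and honest bounds", {
  grid <- run_lorenz_benchmark(n_realizations = 2, seed = 17)
  expect_identical(nrow(grid), 8L)
  expect_setequal(unique(grid$coupling), c("coupled", "uncoupled"))
  expect_setequal(unique(grid$method), c("order_pattern", "correlation"))
  expect_setequal(unique(grid$dimension), c(2L, 6L))
  expect_true(all(grid$rate >= 0 & grid$rate <= 1))
  expect_identical(unique(grid$window), c(30L, 150L))
  # coupled order-pattern rate >= uncoupled at the same dimension
  for (dd in c(2L, 6L)) {
    rc <- grid$rate[grid$coupling == "coupled" & grid$method == "order_pattern" &
                      grid$dimension == dd]
    ru <- grid$rate[grid$coupling == "uncoupled" & grid$method == "order_pattern" &
                      grid$dimension == dd]
    expect_gte(rc, ru)
  }
  # reproducible under the same master seed
  grid2 <- run_lorenz_benchmark(n_realizations = 2, seed = 17)
  expect_identical(grid$rate, grid2$rate)

  # a single realization yields rates, not NaN
  g1 <- run_lorenz_benchmark(n_realizations = 1, seed = 3)
  expect_false(any(is.nan(g1$rate)))
})

test_that("planted groups share symbols exactly inside their epochs", {
  for (seed in c(2, 9, 30)) {
    sim <- generate_synthetic_ensemble(
      8, 600, groups = list(list(channels = 1:4, epoch = c(201, 400)),
                            list(channels = 5:7, epoch = c(401, 550))),
      seed = seed)
    d <- 4; tau <- 5
    sy <- symbolize_set(sim$data, d, tau)
    sched <- expected_component_schedule(sim$truth, 8, 600, d, tau)
    span <- (d - 1) * tau
    # interior anchors of group 1: whole window inside [201, 400]
    for (t in c(201, 300, 400 - span)) {
      expect_identical(length(unique(sy$symbols[t, 1:4])), 1L)
      expect_identical(sched$expected_components[t], 5L)  # 8 - 3 merged
    }
    # outside any epoch nothing is planted
    expect_false(sched$in_epoch[100])
    expect_identical(sched$expected_components[100], 8L)
  }
})

test_that("without planted groups components stay near the channel count", {
  sim <- generate_synthetic_ensemble(10, 400, seed = 13)
  nets <- build_network_sequence(symbolize_set(sim$data, 5, 3))
  counts <- metric_time_series(nets, "n_components")$value
  # chance collisions bounded by pairs/d! = 45/120 per time point
  expect_gt(mean(counts), 10 - 2 * 45 / 120)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("the generator is seeded and validates its group specification", {
  g <- list(list(channels = 1:2, epoch = c(10, 50)))
  s1 <- generate_synthetic_ensemble(4, 100, g, seed = 3)
  s2 <- generate_synthetic_ensemble(4, 100, g, seed = 3)
  expect_identical(s1$data$values, s2$data$values)

  expect_error(generate_synthetic_ensemble(
    4, 100, list(list(channels = 1:2, epoch = c(10, 50)),
                 list(channels = 2:3, epoch = c(40, 80)))),
    "overlapping")
  expect_error(generate_synthetic_ensemble(
    4, 100, list(list(channels = 1:9, epoch = c(10, 50)))), "out of range")
  expect_error(generate_synthetic_ensemble(
    4, 100, list(list(channels = 1:2, epoch = c(0, 50)))), "epoch")
  # non-contradictory reuse of a channel in disjoint epochs is fine
  ok <- generate_synthetic_ensemble(
    4, 100, list(list(channels = 1:2, epoch = c(10, 40)),
                 list(channels = 2:3, epoch = c(60, 90))))
  expect_identical(nrow(ok$truth), 2L)
})

test_that("run-through: planted epoch appears as a component-count dip", {
  sim <- generate_synthetic_ensemble(
    9, 500, groups = list(list(channels = 1:5, epoch = c(151, 350))), seed = 31)
  d <- 5; tau <- 4
  nets <- build_network_sequence(symbolize_set(sim$data, d, tau))
  counts <- metric_time_series(nets, "n_components")$value
  sched <- expected_component_schedule(sim$truth, 9, 500, d, tau)
  # inside the epoch interior the 5 planted channels collapse to 1 component
  expect_true(all(counts[sched$in_epoch] <= 5))
  # outside, the network is (nearly) fully segregated
  expect_gt(mean(counts[!sched$in_epoch]), 8)
})
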