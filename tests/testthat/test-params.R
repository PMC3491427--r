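test_that("mutual_information matches the literal histogram oracle", {
  set.seed(5)
  u <- cumsum(rnorm(400))
  for (lag in c(0, 3, 11)) {
    for (nb in c(8, 32)) {
      expect_equal(mutual_information(u, lag, nb), oracle_mi(u, lag, nb),
                   tolerance = 1e-12)
    }
  }
})

test_that("MI at lag 0 equals the binned Shannon entropy", {
  set.seed(8)
  u <- rnorm(1000)
  for (nb in c(5, 20, 100)) {
    p <- table(cut(u, seq(min(u), max(u), length.out = nb + 1),
                   include.lowest = TRUE)) / length(u)
    p <- p[p > 0]
    expect_equal(mutual_information(u, 0, nb), -sum(p * log2(p)),
                 tolerance = 1e-12)
  }
})

test_that("MI of an i.i.d. series at positive lag is near zero", {
  set.seed(13)
  u <- rnorm(20000)
  expect_lt(mutual_information(u, 10, 16), 0.03)  # estimator bias only
  expect_gt(mutual_information(u, 10, 16), 0)
})

test_that("constant series gives MI 0 with a degenerate-histogram warning", {
  expect_warning(v <- mutual_information(rep(2, 50), 3, 10), "degenerate")
  expect_identical(v, 0)
})

test_that("estimate_delay finds the sine MI minimum near a quarter period", {
  set.seed(1)
  t <- seq_len(10000)
  u <- sin(2 * pi * t / 100) + 0.3 * rnorm(10000)  # period 100 samples
  tau <- estimate_delay(u, max_lag = 60, n_bins = 20)
  expect_gte(as.integer(tau), 20)
  expect_lte(as.integer(tau), 30)
})

test_that("monotone MI profiles fall back to the global arg-min with a warning", {
  set.seed(2)
  ar <- as.numeric(stats::filter(rnorm(3000), 0.95, method = "recursive"))
  expect_warning(fb <- estimate_delay(ar, max_lag = 5, n_bins = 30), "no local")
  expect_identical(as.integer(fb),
                   as.integer(which.min(attr(fb, "mi_profile")[-1])))
})

test_that("too few histogram bins inflate the delay estimate", {
  set.seed(21)
  for (rep in 1:3) {
    u <- as.numeric(stats::filter(rnorm(4000), rep(1 / 20, 20), sides = 1))
    u <- u[!is.na(u)]
    coarse <- as.integer(suppressWarnings(estimate_delay(u, max_lag = 80, n_bins = 10)))
    fine <- as.integer(suppressWarnings(estimate_delay(u, max_lag = 80, n_bins = 100)))
    expect_gte(coarse, fine)
  }
})

test_that("FNN separates noise from deterministic signals", {
  set.seed(2)
  noise <- rnorm(500)
  fr <- vapply(1:6, function(d) fnn_fraction(noise, d, 1), numeric(1))
  expect_true(all(fr > 0.1))  # white noise never unfolds
  expect_warning(dn <- estimate_dimension(noise, tau = 1, max_d = 8), "never fell")
  expect_identical(as.integer(dn), 8L)
  expect_false(attr(dn, "converged"))

  t <- seq(0, 40 * pi, length.out = 2000)
  sine <- sin(t)
  expect_lt(fnn_fraction(sine, 2, 10), 0.01)
  ds <- estimate_dimension(sine, tau = 10, max_d = 6)
  expect_identical(as.integer(ds), 2L)
  expect_true(attr(ds, "converged"))

  ramp <- seq_len(300) / 10
  expect_identical(as.integer(estimate_dimension(ramp, tau = 2, max_d = 6)), 2L)
})

test_that("fnn_fraction agrees with a brute-force nearest-neighbour oracle", {
  set.seed(17)
  u <- as.numeric(stats::filter(rnorm(320), 0.8, method = "recursive"))
  d <- 2L; tau <- 3L; rtol <- 10; atol <- 2
  L <- length(u) - d * tau
  n_false <- 0
  for (i in seq_len(L)) {
    best <- Inf; best_j <- NA
    for (j in seq_len(L)) {
      if (abs(i - j) <= tau) next
      dist_ij <- sqrt((u[i] - u[j])^2 + (u[i + tau] - u[j + tau])^2)
      if (dist_ij < best) { best <- dist_ij; best_j <- j }
    }
    gain <- abs(u[i + d * tau] - u[best_j + d * tau])
    if (gain / best > rtol || sqrt(best^2 + gain^2) / sd(u) > atol) {
      n_false <- n_false + 1
    }
  }
  expect_equal(fnn_fraction(u, d, tau), n_false / L, tolerance = 1e-12)
})

test_that("estimate_dimension is monotone in the threshold", {
  set.seed(31)
  u <- as.numeric(stats::filter(rnorm(600), c(0.5, 0.3), method = "recursive"))
  prev <- Inf
  for (thr in c(0.005, 0.02, 0.1, 0.3)) {
    d_thr <- suppressWarnings(as.integer(estimate_dimension(u, tau = 2, max_d = 8,
                                                            threshold = thr)))
    expect_lte(d_thr, prev)
    prev <- d_thr
  }
})

test_that("aggregate_params takes the dimension mode and rounded mean delay", {
  p <- aggregate_params(c(2, 3, 3, 3), c(14, 16))
  expect_identical(p$d, 3L)
  expect_identical(p$tau, 15L)
  expect_identical(p$d_hat, 8L)
  expect_identical(p$span, 7L * 15L)

  p2 <- aggregate_params(c(2, 2, 2), c(30, 30))
  expect_identical(p2$d_hat, 6L)

  # single channel passes through
  p3 <- aggregate_params(3, 12)
  expect_identical(c(p3$d, p3$tau), c(3L, 12L))

  # mean rounds half away from zero
  expect_identical(aggregate_params(c(2, 2), c(14, 15))$tau, 15L)

  # ties break toward the smaller dimension, with a message
  expect_message(pt <- aggregate_params(c(2, 2, 3, 3), c(10, 10)), "tied")
  expect_identical(pt$d, 2L)

  # permutation invariance
  set.seed(4)
  dvec <- sample(2:4, 9, replace = TRUE); tvec <- sample(5:40, 9)
  ord <- sample(9)
  pa <- aggregate_params(dvec, tvec)
  pb <- aggregate_params(dvec[ord], tvec[ord])
  expect_identical(pa[c("d", "d_hat", "tau", "span")],
                   pb[c("d", "d_hat", "tau", "span")])

  expect_error(aggregate_params(integer(0), integer(0)), "at least one")
})

test_that("realign_times centres the pattern window", {
  expect_equal(realign_times(0, list(d_hat = 8, tau = 15)), 52.5)
  expect_equal(realign_times(100, list(d_hat = 6, tau = 30)), 175)
  expect_equal(realign_times(7, list(d_hat = 2, tau = 1)), 7.5)
  # ms conversion
  expect_equal(realign_times(100, list(d_hat = 6, tau = 30), sampling_rate = 500),
               350)
  # falls back to d when no over-embedded dimension is recorded
  expect_equal(realign_times(0, list(d = 3, tau = 10)), 10)
})

test_that("Lorenz embedding estimates match the attractor's known scales", {
  x5000 <- lorenz_pair(0, seed = 101, transient = 10000, length = 5000)$x1
  tau <- as.integer(estimate_delay(x5000, max_lag = 60, n_bins = 100))
  expect_gte(tau, 28)
  expect_lte(tau, 36)
  # estimate stabilizes once the bins are fine enough (doubling the count
  # moves it by a few samples at most)
  tau50 <- as.integer(estimate_delay(x5000, max_lag = 60, n_bins = 50))
  expect_lte(abs(tau50 - tau), 4)

  x2000 <- x5000[1:2000]
  dd <- suppressWarnings(estimate_dimension(x2000, tau = 30, max_d = 6))
  expect_true(as.integer(dd) %in% 2:3)
  fr <- attr(dd, "fractions")
  expect_lt(fr[2], 0.1)   # two coordinates nearly unfold the attractor
  expect_gt(fr[1], 0.5)
})

test_that("glance and tidy summarize embedding parameters", {
  p <- aggregate_params(c(2, 3, 3), c(10, 20, 30))
  g <- glance(p)
  expect_identical(g$d, 3L)
  expect_identical(g$tau, 20L)
  expect_identical(g$n_channels, 3L)
  td <- tidy(p)
  expect_identical(nrow(td), 3L)
})
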