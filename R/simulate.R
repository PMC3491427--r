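#' Configuration for the coupled-Lorenz benchmark
#'
#' Two identical Lorenz systems (sigma = 10, r = 28, b = 8/3) diffusively
#' coupled through their first components with strength `g`:
#' `dx1 = 10(x2 - x1) + g(y1 - x1)` and symmetrically for `y1`. `g = 0`
#' leaves two independent chaotic attractors; `g = 5` produces complete
#' synchronization after a transient. The trajectory is integrated with a
#' fixed output step `dt`, down-sampled by keeping every `downsample`-th
#' point, the first `transient` down-sampled points are discarded and the
#' next `length` points of the first components are retained.
#'
#' @param g coupling strength (0 = uncoupled, 5 = fully synchronizing).
#' @param dt integration output step (default 0.001).
#' @param downsample keep-every factor applied after integration (default 5).
#' @param transient leading down-sampled points discarded (default 10000).
#' @param length retained points per series (default 1000).
#' @param x0,y0 base initial states of the two systems.
#' @param jitter half-width of the uniform perturbation added independently
#'   to every component of the initial state (default 0.5).
#' @param seed optional integer seed for the jitter.
#' @return A `lorenz_config` list.
#' @export
lorenz_config <- function(g = 0, dt = 0.001, downsample = 5, transient = 10000,
                          length = 1000, x0 = c(-1, 3, 4), y0 = c(-8, 8, 27),
                          jitter = 0.5, seed = NULL) {
  stopifnot(dt > 0, downsample >= 1, transient >= 0, length >= 1,
            jitter >= 0, base::length(x0) == 3, base::length(y0) == 3)
  structure(list(g = g, dt = dt, downsample = as.integer(downsample),
                 transient = as.integer(transient), length = as.integer(length),
                 x0 = x0, y0 = y0, jitter = jitter, seed = seed),
            class = "lorenz_config")
}

lorenz_rhs <- function(t, s, parms) {
  g <- parms[["g"]]
  list(c(
    10 * (s[2] - s[1]) + g * (s[4] - s[1]),
    s[1] * (28 - s[3]) - s[2],
    s[1] * s[2] - 8 / 3 * s[3],
    10 * (s[5] - s[4]) + g * (s[1] - s[4]),
    s[4] * (28 - s[6]) - s[5],
    s[4] * s[5] - 8 / 3 * s[6]
  ))
}

#' Simulate a pair of coupled Lorenz oscillators
#'
#' Integrates the system of [lorenz_config()] with the adaptive
#' Dormand-Prince 4(5) Runge-Kutta solver (`deSolve`'s `ode45`), applies the
#' down-sampling and transient protocol, and returns the first components of
#' both systems.
#'
#' @param cfg a [lorenz_config()].
#' @return Tibble with columns `time` (model time), `x1`, `y1`, of
#'   `cfg$length` rows.
#' @examples
#' \donttest{
#' xy <- simulate_coupled_lorenz(lorenz_config(g = 5, transient = 1000,
#'                                             length = 200, seed = 1))
#' max(abs(xy$x1 - xy$y1)) # complete synchronization
#' }
#' @export
simulate_coupled_lorenz <- function(cfg) {
  stopifnot(inherits(cfg, "lorenz_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  s0 <- c(cfg$x0, cfg$y0) + stats::runif(6, -cfg$jitter, cfg$jitter)
  n_fine <- cfg$downsample * (cfg$transient + cfg$length)
  times <- seq(0, by = cfg$dt, length.out = n_fine + 1)
  sol <- deSolve::ode(y = s0, times = times, func = lorenz_rhs,
                      parms = list(g = cfg$g), method = "ode45")
  if (!all(is.finite(sol[, -1]))) {
    stop("trajectory blew up (non-finite state); check the configuration", call. = FALSE)
  }
  keep <- seq(1, n_fine + 1, by = cfg$downsample)
  kept <- sol[keep, , drop = FALSE]
  idx <- cfg$transient + seq_len(cfg$length)
  tibble::tibble(time = kept[idx, 1], x1 = kept[idx, 2], y1 = kept[idx, 5])
}

#' Order-pattern link-detection rate between two series
#'
#' Symbolizes both series at the same `(d, tau)` and returns the fraction of
#' symbol time points at which the patterns are identical — the link
#' detection rate of the order-pattern connectivity criterion for this pair.
#'
#' @param x1,y1 numeric series of equal length.
#' @param d pattern dimension.
#' @param tau pattern delay in samples.
#' @return Rate in `[0, 1]`.
#' @export
op_detection_rate <- function(x1, y1, d, tau) {
  stopifnot(length(x1) == length(y1))
  sx <- symbolize_series(x1, d, tau)
  sy <- symbolize_series(y1, d, tau)
  mean(as.integer(sx) == as.integer(sy))
}

#' Windowed-correlation link-detection rate between two series
#'
#' Baseline detector: splits the pair into consecutive non-overlapping
#' windows of `w = (d - 1) * tau` samples (the span of an order pattern at
#' the same parameters), computes the absolute Pearson correlation within
#' each window, and averages over windows. Absolute values are taken since a
#' consistently strong negative correlation equally indicates dependence.
#' A zero-variance window contributes 0 with a warning.
#'
#' @inheritParams op_detection_rate
#' @return Mean windowed `|r|` in `[0, 1]`.
#' @export
cor_detection_rate <- function(x1, y1, d, tau) {
  stopifnot(length(x1) == length(y1))
  w <- (d - 1) * tau
  if (length(x1) < w) stop("series shorter than one window of ", w, " samples", call. = FALSE)
  n_win <- length(x1) %/% w
  r <- numeric(n_win)
  degenerate <- 0L
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * w + 1):(k * w)
    if (stats::sd(x1[idx]) == 0 || stats::sd(y1[idx]) == 0) {
      degenerate <- degenerate + 1L
      r[k] <- 0
    } else {
      r[k] <- abs(stats::cor(x1[idx], y1[idx]))
    }
  }
  if (degenerate > 0) {
    warning(degenerate, " zero-variance window(s) contributed r = 0", call. = FALSE)
  }
  mean(r)
}

#' Lorenz link-detection benchmark grid
#'
#' For each realization: draw jittered initial conditions, integrate the
#' coupled (`g = 5`) and uncoupled (`g = 0`) systems, and score both the
#' order-pattern detector (dimensions `d = 2` and the over-embedded
#' `d_hat = 6`, `tau = 30`) and the windowed-correlation baseline at the
#' matching window sizes (30 and 150 samples). The coupled cells measure
#' sensitivity; the uncoupled cells measure the false-positive level, where
#' over-embedding is what separates the two detectors.
#'
#' @param n_realizations number of seeded realizations per coupling.
#' @param seed integer master seed; per-realization seeds are derived from it.
#' @param dims order-pattern dimensions to score (default `c(2, 6)`).
#' @param tau pattern delay in samples (default 30).
#' @return Tibble with columns `coupling` ("coupled"/"uncoupled"), `g`,
#'   `method`, `dimension`, `window`, `rate` (mean over realizations), `sd`,
#'   `n_realizations`; per-realization rates in attribute `per_realization`.
#' @examples
#' \donttest{
#' run_lorenz_benchmark(n_realizations = 3, seed = 7)
#' }
#' @export
run_lorenz_benchmark <- function(n_realizations, seed = 1, dims = c(2L, 6L),
                                 tau = 30L) {
  stopifnot(n_realizations >= 1)
  set.seed(seed)
  real_seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_realizations),
                       nrow = n_realizations)
  grid <- list()
  for (ci in 1:2) {
    g <- c(5, 0)[ci]
    rates <- array(NA_real_, dim = c(n_realizations, length(dims), 2),
                   dimnames = list(NULL, paste0("d", dims),
                                   c("order_pattern", "correlation")))
    for (r in seq_len(n_realizations)) {
      xy <- simulate_coupled_lorenz(lorenz_config(g = g, seed = real_seeds[r, ci]))
      for (di in seq_along(dims)) {
        rates[r, di, 1] <- op_detection_rate(xy$x1, xy$y1, dims[di], tau)
        rates[r, di, 2] <- cor_detection_rate(xy$x1, xy$y1, dims[di], tau)
      }
    }
    grid[[ci]] <- tidyr::expand_grid(
      coupling = c("coupled", "uncoupled")[ci], g = g,
      method = c("order_pattern", "correlation"), dimension = as.integer(dims)
    ) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        window = (.data$dimension - 1L) * as.integer(tau),
        rate = mean(rates[, paste0("d", .data$dimension), .data$method]),
        sd = stats::sd(rates[, paste0("d", .data$dimension), .data$method])
      ) |>
      dplyr::ungroup()
    attr(grid[[ci]], "rates") <- rates
  }
  out <- dplyr::bind_rows(grid)
  out$n_realizations <- n_realizations
  attr(out, "per_realization") <- list(coupled = attr(grid[[1]], "rates"),
                                       uncoupled = attr(grid[[2]], "rates"))
  attr(out, "seed") <- seed
  out
}

#' Synthetic multichannel ensemble with planted synchronization epochs
#'
#' Generates `n_channels` independent smooth noise channels of length `T`.
#' Within each planted group's epoch, every member channel is replaced by a
#' channel-specific strictly increasing distortion of one shared group
#' waveform, so the members' order-pattern symbols are *exactly* identical
#' there while amplitudes differ — emulating functionally coupled channels
#' seen through different gains and monotone sensor nonlinearities. Outside
#' their epochs channels are independent, so the expected component count is
#' (almost) the number of channels.
#'
#' @param n_channels number of channels (N).
#' @param T_len samples per channel.
#' @param groups list of planted groups, each a list with `channels`
#'   (integer indices) and `epoch` (`c(start, end)` sample interval). A
#'   channel may not belong to two groups with overlapping epochs.
#' @param noise_sd scale of the independent background signals.
#' @param distort logical: apply random monotone amplitude distortions to
#'   group members (default TRUE; symbols are unaffected either way).
#' @param seed optional integer seed.
#' @return List with `data` (a [ts_set()]) and `truth` (tibble with one row
#'   per group: `group`, `channels` (list-column), `start`, `end`).
#' @seealso [expected_component_schedule()] for the implied per-time ground
#'   truth at a given `(d, tau)`.
#' @examples
#' sim <- generate_synthetic_ensemble(
#'   6, 300, groups = list(list(channels = 1:3, epoch = c(101, 200))), seed = 1)
#' sim$data
#' @export
generate_synthetic_ensemble <- function(n_channels, T_len, groups = list(),
                                        noise_sd = 1, distort = TRUE,
                                        seed = NULL) {
  stopifnot(n_channels >= 1, T_len >= 2)
  if (!is.null(seed)) set.seed(seed)
  check_groups(groups, n_channels, T_len)
  smooth_noise <- function(n) {
    as.numeric(stats::filter(stats::rnorm(n), 0.9, method = "recursive"))
  }
  values <- matrix(0, nrow = n_channels, ncol = T_len)
  for (i in seq_len(n_channels)) values[i, ] <- noise_sd * smooth_noise(T_len)
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    ep <- grp$epoch[1]:grp$epoch[2]
    waveform <- smooth_noise(length(ep))
    for (ch in grp$channels) {
      if (distort) {
        a <- stats::runif(1, 0.5, 2)
        cc <- stats::runif(1, 0, 0.5)
        b <- stats::rnorm(1, 0, 2)
        values[ch, ep] <- a * waveform + cc * tanh(waveform) + b
      } else {
        values[ch, ep] <- waveform
      }
    }
  }
  truth <- tibble::tibble(
    group = seq_along(groups),
    channels = purrr::map(groups, "channels"),
    start = purrr::map_int(groups, ~as.integer(.x$epoch[1])),
    end = purrr::map_int(groups, ~as.integer(.x$epoch[2]))
  )
  list(data = ts_set(values), truth = truth)
}

check_groups <- function(groups, n_channels, T_len) {
  seen <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    if (is.null(grp$channels) || is.null(grp$epoch) || length(grp$epoch) != 2) {
      stop("each group needs `channels` and `epoch = c(start, end)`", call. = FALSE)
    }
    if (grp$epoch[1] < 1 || grp$epoch[2] > T_len || grp$epoch[1] > grp$epoch[2]) {
      stop("group ", gi, ": epoch must lie within [1, ", T_len, "]", call. = FALSE)
    }
    if (any(grp$channels < 1) || any(grp$channels > n_channels)) {
      stop("group ", gi, ": channel indices out of range", call. = FALSE)
    }
    for (ch in grp$channels) {
      prev <- seen[[as.character(ch)]]
      if (!is.null(prev) &&
          grp$epoch[1] <= prev[2] && prev[1] <= grp$epoch[2]) {
        stop("channel ", ch, " assigned to two groups with overlapping epochs",
             call. = FALSE)
      }
      seen[[as.character(ch)]] <- grp$epoch
    }
  }
  invisible(TRUE)
}

#' Expected component-count schedule for a planted ensemble
#'
#' Translates the generator's ground truth into the component count expected
#' at every symbol time point for a given `(d, tau)`: a group's channels are
#' guaranteed to share one symbol (hence merge into one component) exactly at
#' the anchors whose full pattern window lies inside the group's epoch.
#' Outside those anchors the expectation is `n_channels` up to chance symbol
#' collisions between independent channels (probability at most
#' `choose(N, 2) / d!` per time point under a uniform-symbol bound).
#'
#' @param truth the `truth` tibble from [generate_synthetic_ensemble()].
#' @param n_channels total number of channels.
#' @param T_len samples per channel.
#' @param d,tau symbolization parameters to be used on the data.
#' @return Tibble with columns `t` (anchor index, `1:(T_len - (d-1) tau)`),
#'   `expected_components`, and `in_epoch` (logical: any group fully covers
#'   the window at `t`).
#' @export
expected_component_schedule <- function(truth, n_channels, T_len, d, tau) {
  span <- (d - 1) * tau
  L <- T_len - span
  stopifnot(L >= 1)
  expected <- rep(as.integer(n_channels), L)
  inside <- rep(FALSE, L)
  for (gi in seq_len(nrow(truth))) {
    t_lo <- truth$start[gi]
    t_hi <- truth$end[gi] - span
    if (t_hi < t_lo) next
    idx <- max(1, t_lo):min(L, t_hi)
    expected[idx] <- expected[idx] - (length(truth$channels[[gi]]) - 1L)
    inside[idx] <- TRUE
  }
  tibble::tibble(t = seq_len(L), expected_components = expected,
                 in_epoch = inside)
}
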