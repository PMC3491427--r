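#' False-nearest-neighbour fraction at a given embedding dimension
#'
#' Delay-embeds the series in dimension `d`, finds every point's nearest
#' neighbour (Euclidean metric, excluding temporal neighbours within one
#' delay — a Theiler window), and flags the neighbour as "false" when adding
#' the (d+1)-th delay coordinate separates the pair: either the distance
#' gain relative to the d-dimensional distance exceeds `rtol`, or the
#' (d+1)-dimensional distance exceeds `atol` standard deviations of the
#' series. The fraction of false neighbours drops to ~0 once `d` is large
#' enough to unfold the attractor.
#'
#' @param u numeric series.
#' @param d candidate embedding dimension, >= 1.
#' @param tau embedding delay in samples.
#' @param rtol relative distance-growth criterion (default 10).
#' @param atol absolute criterion in units of sd(u) (default 2).
#' @return Fraction in `[0, 1]` of embedded points whose nearest neighbour is
#'   false.
#' @references Kennel, Brown & Abarbanel's false-nearest-neighbour test.
#' @export
fnn_fraction <- function(u, d, tau, rtol = 10, atol = 2) {
  stopifnot(is.numeric(u), d >= 1, tau >= 1)
  d <- as.integer(d); tau <- as.integer(tau)
  L <- length(u) - d * tau  # need the (d+1)-th coordinate too
  if (L < 2) {
    stop("series of length ", length(u), " too short for FNN at d = ", d,
         ", tau = ", tau, "; need length > d*tau + 1", call. = FALSE)
  }
  emb <- matrix(0, nrow = L, ncol = d)
  for (k in 0:(d - 1)) emb[, k + 1] <- u[seq_len(L) + k * tau]
  nxt <- u[seq_len(L) + d * tau]
  D <- as.matrix(stats::dist(emb))
  diag(D) <- Inf
  # Theiler window: exclude temporally adjacent points from the neighbour search
  theiler <- tau
  for (i in seq_len(L)) {
    lo <- max(1L, i - theiler); hi <- min(L, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- apply(D, 1, which.min)
  r_d <- D[cbind(seq_len(L), nn)]
  gain <- abs(nxt - nxt[nn])
  sigma <- stats::sd(u)
  if (sigma == 0) return(0)
  is_false <- (gain / r_d > rtol) | (sqrt(r_d^2 + gain^2) / sigma > atol)
  mean(is_false)
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' Returns the smallest dimension whose false-neighbour fraction falls at or
#' below `threshold`. If no dimension up to `max_d` qualifies, `max_d` is
#' returned with `converged = FALSE` (typical for white noise, whose
#' false-neighbour fraction stays high at any dimension).
#'
#' @inheritParams fnn_fraction
#' @param max_d largest dimension to try (>= 2).
#' @param threshold acceptable false-neighbour fraction (default 0.01).
#' @return Integer dimension with attributes `converged` (logical) and
#'   `fractions` (the FNN profile over `1:d`).
#' @export
estimate_dimension <- function(u, tau, max_d = 8, threshold = 0.01,
                               rtol = 10, atol = 2) {
  stopifnot(max_d >= 2)
  fracs <- numeric(0)
  for (d in seq_len(max_d)) {
    f <- fnn_fraction(u, d, tau, rtol = rtol, atol = atol)
    fracs[d] <- f
    if (d >= 2 && f <= threshold) {
      return(structure(as.integer(d), converged = TRUE, fractions = fracs))
    }
  }
  warning("FNN fraction never fell below ", threshold, " up to d = ", max_d,
          "; returning max_d (series may be noise-dominated)", call. = FALSE)
  structure(as.integer(max_d), converged = FALSE, fractions = fracs)
}

#' Auto-mutual-information at a given lag
#'
#' Histogram estimate (equal-width bins over each marginal's range) of the
#' mutual information, in bits, between `u(t)` and `u(t + lag)`. Used to pick
#' the embedding delay at the first local minimum of the lag profile.
#'
#' @param u numeric series.
#' @param lag non-negative integer lag in samples.
#' @param n_bins number of histogram bins per marginal (default 100). Too few
#'   bins inflate delay estimates; estimates stabilize as bins increase.
#' @return Mutual information in bits (>= 0 up to estimator noise). At
#'   `lag = 0` this equals the Shannon entropy of the binned series.
#' @export
mutual_information <- function(u, lag, n_bins = 100) {
  stopifnot(is.numeric(u), lag >= 0, n_bins >= 2)
  lag <- as.integer(lag); n_bins <- as.integer(n_bins)
  n <- length(u) - lag
  if (n < 2) stop("lag ", lag, " leaves fewer than 2 overlapping samples", call. = FALSE)
  a <- u[seq_len(n)]
  b <- u[seq_len(n) + lag]
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    warning("constant series: degenerate single-bin histogram, MI = 0", call. = FALSE)
    return(0)
  }
  ia <- bin_index(a, n_bins)
  ib <- bin_index(b, n_bins)
  joint <- tabulate((ia - 1L) * n_bins + ib, nbins = n_bins * n_bins) / n
  pa <- tabulate(ia, nbins = n_bins) / n
  pb <- tabulate(ib, nbins = n_bins) / n
  nz <- which(joint > 0)
  ia_nz <- (nz - 1L) %/% n_bins + 1L
  ib_nz <- (nz - 1L) %% n_bins + 1L
  sum(joint[nz] * log2(joint[nz] / (pa[ia_nz] * pb[ib_nz])))
}

bin_index <- function(x, n_bins) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Estimate the embedding delay from the first minimum of auto-MI
#'
#' Scans lags `0:max_lag` and returns the smallest lag `l >= 2` with
#' `MI(l) < MI(l - 1)` and `MI(l) <= MI(l + 1)` — the first local minimum of
#' the auto-mutual-information profile. If the profile has no local minimum
#' in range (e.g. monotone decay), the arg-min over the scanned range is
#' returned with a warning.
#'
#' @inheritParams mutual_information
#' @param max_lag largest lag to scan (>= 2).
#' @return Integer delay in samples, with attribute `mi_profile` (MI at lags
#'   `0:max_lag`).
#' @export
estimate_delay <- function(u, max_lag = 100, n_bins = 100) {
  stopifnot(max_lag >= 2)
  max_lag <- as.integer(max_lag)
  prof <- vapply(0:max_lag, function(l) mutual_information(u, l, n_bins), numeric(1))
  mi <- function(l) prof[l + 1]
  for (l in 2:(max_lag - 1)) {
    if (mi(l) < mi(l - 1) && mi(l) <= mi(l + 1)) {
      return(structure(as.integer(l), mi_profile = prof))
    }
  }
  warning("no local MI minimum in lags 2..", max_lag - 1,
          "; returning the global arg-min of the scanned range", call. = FALSE)
  structure(as.integer(which.min(prof[-1])), mi_profile = prof)
}

#' Aggregate per-channel embedding estimates
#'
#' Combines channel-wise dimension and delay estimates into one set of
#' parameters for the whole recording: the mode of the dimensions (ties
#' broken toward the smaller, cheaper dimension), the rounded mean of the
#' delays (half away from zero), and the over-embedded dimension
#' `d_hat = 2d + 2`. Over-embedding deliberately uses a larger pattern than
#' the attractor needs, which copes with non-stationarity and suppresses
#' chance symbol matches between independent channels.
#'
#' @param per_channel_d integer vector of per-channel dimension estimates.
#' @param per_channel_tau integer vector of per-channel delay estimates
#'   (samples).
#' @return An `embedding_params` object: list with `per_channel_d`,
#'   `per_channel_tau`, `d` (mode), `d_hat = 2d + 2`, `tau` (rounded mean)
#'   and `span = (d_hat - 1) * tau` (samples).
#' @examples
#' p <- aggregate_params(c(2, 3, 3, 3), c(14, 16))
#' p$d_hat # 8
#' p$tau   # 15
#' @export
aggregate_params <- function(per_channel_d, per_channel_tau) {
  if (length(per_channel_d) == 0 || length(per_channel_tau) == 0) {
    stop("need at least one dimension and one delay estimate", call. = FALSE)
  }
  stopifnot(all(per_channel_d >= 2), all(per_channel_tau >= 1))
  counts <- table(per_channel_d)
  modes <- as.integer(names(counts)[counts == max(counts)])
  d <- min(modes)
  if (length(modes) > 1) {
    message("dimension mode tied between {", paste(sort(modes), collapse = ", "),
            "}; using the smaller, d = ", d)
  }
  mean_tau <- mean(per_channel_tau)
  tau <- as.integer(sign(mean_tau) * floor(abs(mean_tau) + 0.5))  # half away from zero
  d_hat <- 2L * d + 2L
  structure(
    list(per_channel_d = as.integer(per_channel_d),
         per_channel_tau = as.integer(per_channel_tau),
         d = d, d_hat = d_hat, tau = tau, span = (d_hat - 1L) * tau),
    class = "embedding_params"
  )
}

#' Estimate embedding parameters for every channel of a recording
#'
#' Runs [estimate_delay()] and then [estimate_dimension()] (at that channel's
#' delay) on each channel and aggregates with [aggregate_params()].
#'
#' @param x a `ts_set` or numeric matrix (channels in rows).
#' @inheritParams estimate_dimension
#' @inheritParams estimate_delay
#' @return An `embedding_params` object (see [aggregate_params()]).
#' @export
estimate_embedding <- function(x, max_d = 8, max_lag = 100, n_bins = 100,
                               threshold = 0.01) {
  if (is.matrix(x)) x <- ts_set(x)
  stopifnot(inherits(x, "ts_set"))
  taus <- integer(nrow(x$values))
  dims <- integer(nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    ui <- x$values[i, ]
    taus[i] <- estimate_delay(ui, max_lag = max_lag, n_bins = n_bins)
    dims[i] <- estimate_dimension(ui, tau = taus[i], max_d = max_d,
                                  threshold = threshold)
  }
  out <- aggregate_params(dims, taus)
  out$labels <- x$labels
  out
}

#' Realign a pattern timestamp to the window centre
#'
#' A pattern anchored at sample `t` summarizes the span
#' `Delta_t = (d - 1) * tau` samples ahead of `t`; for display against the
#' original time axis the timestamp is moved to the middle of that window:
#' `t* = t + Delta_t / 2` (kept fractional). With a sampling rate the result
#' is converted to milliseconds.
#'
#' @param t anchor sample index (scalar or vector).
#' @param params an `embedding_params` object, or a list with elements
#'   `d_hat` (or `d`) and `tau` giving the dimension actually used to build
#'   the patterns.
#' @param sampling_rate samples per second; when given, the result is in ms.
#' @return Realigned time(s): fractional samples, or milliseconds when
#'   `sampling_rate` is supplied.
#' @examples
#' realign_times(0, list(d_hat = 8, tau = 15))   # 52.5
#' realign_times(100, list(d_hat = 6, tau = 30)) # 175
#' @export
realign_times <- function(t, params, sampling_rate = NULL) {
  d_used <- if (!is.null(params$d_hat)) params$d_hat else params$d
  stopifnot(!is.null(d_used), !is.null(params$tau))
  span <- (d_used - 1) * params$tau
  t_star <- t + span / 2
  if (!is.null(sampling_rate)) t_star <- t_star / sampling_rate * 1000
  t_star
}

#' @export
print.embedding_params <- function(x, ...) {
  cat("<embedding_params> d = ", x$d, " (mode of ", length(x$per_channel_d),
      " channels), d_hat = 2d + 2 = ", x$d_hat, ", tau = ", x$tau,
      " samples (mean), span = ", x$span, " samples\n", sep = "")
  invisible(x)
}

#' One-row summary of aggregated embedding parameters
#'
#' @param x an `embedding_params` object.
#' @param ... unused.
#' @return One-row tibble with `d`, `d_hat`, `tau`, `span` and `n_channels`.
#' @method glance embedding_params
#' @export
glance.embedding_params <- function(x, ...) {
  tibble::tibble(d = x$d, d_hat = x$d_hat, tau = x$tau, span = x$span,
                 n_channels = length(x$per_channel_d))
}

#' Per-channel embedding estimates as a tibble
#'
#' @param x an `embedding_params` object.
#' @param ... unused.
#' @return Tibble with one row per channel: `channel`, `d`, `tau`.
#' @method tidy embedding_params
#' @export
tidy.embedding_params <- function(x, ...) {
  n <- max(length(x$per_channel_d), length(x$per_channel_tau))
  tibble::tibble(
    channel = if (!is.null(x$labels)) x$labels else paste0("ch", seq_len(n)),
    d = rep_len(x$per_channel_d, n),
    tau = rep_len(x$per_channel_tau, n)
  )
}
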