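#' Order pattern of a single window
#'
#' Returns the rank of each position among the `d` values of a window, with
#' rank 1 for the smallest value. The rank word is the order pattern: for
#' `d = 2` the increasing window maps to pattern `(1, 2)` and the decreasing
#' one to `(2, 1)`. Ties are broken by position: the earlier sample receives
#' the smaller rank, so integer-valued or quantized inputs behave
#' reproducibly.
#'
#' @param window numeric vector of at least 2 finite values.
#' @return Integer vector of ranks, a permutation of `1:length(window)`.
#' @examples
#' rank_pattern(c(1, 3, 2)) # 1 3 2, the "132" pattern
#' rank_pattern(c(5, 7))    # 1 2, an increase
#' @seealso [pattern_index()] for the integer encoding of a pattern.
#' @export
rank_pattern <- function(window) {
  if (!is.numeric(window) || length(window) < 2) {
    stop("`window` must be a numeric vector with at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(window))) {
    stop("`window` contains non-finite values; order patterns are undefined for NA/NaN/Inf",
         call. = FALSE)
  }
  as.integer(rank(window, ties.method = "first"))
}

#' Integer encoding of an order pattern
#'
#' Maps a rank word (a permutation of `1:d`) to its lexicographic rank among
#' all `d!` permutations, an integer in `0:(factorial(d) - 1)`. The identity
#' pattern `1 2 ... d` maps to 0. `pattern_unrank()` is the inverse.
#'
#' The encoding is a pure serialization convention: any bijection between
#' patterns and integers yields the same networks, since links only require
#' symbol identity. Lexicographic rank (the Lehmer code) is pinned so symbol
#' files are portable.
#'
#' @param label integer vector forming a permutation of `1:d`, or a string of
#'   single digits such as `"132"` (only for `d <= 9`).
#' @return `pattern_index()`: integer in `0:(factorial(d) - 1)`.
#' @examples
#' pattern_index(c(1, 2, 3)) # 0
#' pattern_index("132")      # 1
#' pattern_unrank(5, 3)      # 3 2 1
#' @export
pattern_index <- function(label) {
  if (is.character(label)) {
    stopifnot(length(label) == 1)
    label <- as.integer(strsplit(label, "")[[1]])
  }
  d <- length(label)
  if (d < 2 || anyNA(label) || !setequal(label, seq_len(d))) {
    stop("`label` must be a permutation of 1..d with d >= 2", call. = FALSE)
  }
  label <- as.integer(label)
  idx <- 0L
  for (j in seq_len(d - 1)) {
    smaller_later <- sum(label[(j + 1):d] < label[j])
    idx <- idx + smaller_later * factorial(d - j)
  }
  as.integer(idx)
}

#' @rdname pattern_index
#' @param index integer in `0:(factorial(d) - 1)`.
#' @param d pattern dimension.
#' @return `pattern_unrank()`: the rank word, an integer permutation of `1:d`.
#' @export
pattern_unrank <- function(index, d) {
  stopifnot(length(index) == 1, length(d) == 1, d >= 2)
  index <- as.integer(index)
  if (index < 0 || index >= factorial(d)) {
    stop("`index` must lie in [0, d! - 1]", call. = FALSE)
  }
  remaining <- seq_len(d)
  out <- integer(d)
  for (j in seq_len(d)) {
    f <- factorial(d - j)
    pick <- index %/% f
    index <- index %% f
    out[j] <- remaining[pick + 1]
    remaining <- remaining[-(pick + 1)]
  }
  out
}

# Vectorized encoder: u (numeric vector) -> integer symbols of length
# T - (d-1)*tau. Works column-wise over all windows at once; O(d^2) vector
# passes instead of one rank() call per window.
encode_op <- function(u, d, tau) {
  T_len <- length(u)
  L <- T_len - (d - 1) * tau
  # window matrix: L rows, d columns (column k+1 holds u[t + k*tau])
  W <- matrix(0, nrow = L, ncol = d)
  for (k in 0:(d - 1)) W[, k + 1] <- u[seq_len(L) + k * tau]
  # rank word per window, ties to the earlier position
  R <- matrix(1L, nrow = L, ncol = d)
  tied <- logical(L)
  for (j in seq_len(d)) {
    for (k in seq_len(d)) {
      if (k == j) next
      eq <- W[, k] == W[, j]
      if (k < j) {
        R[, j] <- R[, j] + ((W[, k] < W[, j]) | eq)
      } else {
        R[, j] <- R[, j] + (W[, k] < W[, j])
      }
      tied <- tied | eq
    }
  }
  # Lehmer code -> lexicographic index
  idx <- numeric(L)
  for (j in seq_len(d - 1)) {
    cj <- integer(L)
    for (k in (j + 1):d) cj <- cj + (R[, k] < R[, j])
    idx <- idx + cj * factorial(d - j)
  }
  list(symbols = as.integer(idx), n_tied = sum(tied))
}

check_symbolize_args <- function(T_len, d, tau) {
  stopifnot(length(d) == 1, length(tau) == 1)
  if (d < 2 || d != round(d)) stop("`d` must be an integer >= 2", call. = FALSE)
  if (tau < 1 || tau != round(tau)) stop("`tau` must be an integer >= 1", call. = FALSE)
  need <- (d - 1) * tau + 1
  if (T_len < need) {
    stop("series of length ", T_len, " too short for d = ", d, ", tau = ", tau,
         "; need at least T = (d-1)*tau + 1 = ", need, " samples", call. = FALSE)
  }
  invisible(TRUE)
}

#' Symbolize a single series into order patterns
#'
#' Slides a window of `d` samples spaced `tau` apart along the series and
#' encodes each window's rank structure as an integer symbol in
#' `0:(factorial(d) - 1)` (see [pattern_index()]). The symbol at position `t`
#' is anchored at the window's first sample, i.e. it describes
#' `u(t), u(t + tau), ..., u(t + (d-1)tau)`; use [realign_times()] to move
#' timestamps to the window centre for display.
#'
#' Because only ranks enter the encoding, the output is invariant under any
#' strictly increasing transformation of the amplitudes, and hence robust to
#' monotone drifts and amplitude distortions.
#'
#' @param u numeric vector of length `T > (d-1)*tau`, all values finite.
#' @param d pattern dimension (number of samples per pattern), integer >= 2.
#' @param tau delay between pattern samples, in samples, integer >= 1.
#' @return Integer vector of length `T - (d-1)*tau` with attributes `d`,
#'   `tau` and `start_index` (always 1: the anchor of the first pattern).
#' @examples
#' symbolize_series(c(1, 3, 2), d = 2, tau = 1) # 0 1: up then down
#' length(symbolize_series(rnorm(1400), d = 8, tau = 15)) # 1295
#' @export
symbolize_series <- function(u, d, tau) {
  if (!is.numeric(u)) stop("`u` must be numeric", call. = FALSE)
  check_symbolize_args(length(u), d, tau)
  if (!all(is.finite(u))) {
    bad <- which(!is.finite(u))[1]
    stop("non-finite value at sample ", bad,
         "; gaps would desynchronize channels, clean the data first", call. = FALSE)
  }
  enc <- encode_op(u, as.integer(d), as.integer(tau))
  if (enc$n_tied > 0) {
    warning(enc$n_tied, " of ", length(enc$symbols),
            " windows contained tied values; ties broken by position (earlier sample ranks lower)",
            call. = FALSE)
  }
  structure(enc$symbols, d = as.integer(d), tau = as.integer(tau), start_index = 1L)
}

#' Symbolize every channel of a multichannel recording
#'
#' Applies [symbolize_series()] row-wise to a [ts_set()] (or plain matrix
#' with channels in rows), producing one aligned symbol sequence per channel.
#' All sequences share `d`, `tau`, anchor and length, which is what makes the
#' per-time-point symbol comparison of the network construction meaningful.
#'
#' @param x a `ts_set`, or a numeric matrix with channels in rows.
#' @inheritParams symbolize_series
#' @return An `op_symbols` object: list with `symbols` (L x N integer matrix,
#'   one column per channel, L = T - (d-1)*tau), `labels`, `d`, `tau`,
#'   `start_index` and `sampling_rate`.
#' @examples
#' x <- ts_set(matrix(rnorm(400), nrow = 4))
#' sy <- symbolize_set(x, d = 3, tau = 2)
#' dim(sy$symbols)
#' @export
symbolize_set <- function(x, d, tau) {
  if (is.matrix(x)) x <- ts_set(x)
  stopifnot(inherits(x, "ts_set"))
  check_symbolize_args(ncol(x$values), d, tau)
  d <- as.integer(d); tau <- as.integer(tau)
  L <- ncol(x$values) - (d - 1) * tau
  out <- matrix(NA_integer_, nrow = L, ncol = nrow(x$values))
  tied_channels <- character(0)
  for (i in seq_len(nrow(x$values))) {
    ui <- x$values[i, ]
    if (!all(is.finite(ui))) {
      stop("channel '", x$labels[i], "': non-finite value at sample ",
           which(!is.finite(ui))[1], call. = FALSE)
    }
    enc <- encode_op(ui, d, tau)
    if (enc$n_tied > 0) tied_channels <- c(tied_channels, x$labels[i])
    out[, i] <- enc$symbols
  }
  if (length(tied_channels) > 0) {
    warning("tied values within pattern windows on channel(s) ",
            paste(tied_channels, collapse = ", "),
            "; ties broken by position", call. = FALSE)
  }
  colnames(out) <- x$labels
  structure(
    list(symbols = out, labels = x$labels, d = d, tau = tau,
         start_index = 1L, sampling_rate = x$sampling_rate),
    class = "op_symbols"
  )
}

#' @export
print.op_symbols <- function(x, ...) {
  cat("<op_symbols> ", ncol(x$symbols), " channel(s) x ", nrow(x$symbols),
      " symbols (d = ", x$d, ", tau = ", x$tau, ", alphabet size ",
      factorial(x$d), ")\n", sep = "")
  invisible(x)
}

#' Tidy symbol sequences into a long tibble
#'
#' @param x an `op_symbols` object from [symbolize_set()].
#' @param ... unused.
#' @return Tibble with columns `channel`, `t` (anchor sample index) and
#'   `symbol`.
#' @method tidy op_symbols
#' @export
tidy.op_symbols <- function(x, ...) {
  L <- nrow(x$symbols)
  tibble::tibble(
    channel = rep(x$labels, each = L),
    t = rep(seq_len(L) + x$start_index - 1L, times = ncol(x$symbols)),
    symbol = as.vector(x$symbols)
  )
}
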