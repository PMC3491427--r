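#' Multichannel time-series container
#'
#' Bundles an N x T real-valued matrix (rows = channels) with channel labels
#' and an optional sampling rate. This is the raw input object for the whole
#' pipeline; every downstream step (parameter estimation, symbolization,
#' network construction) accepts it.
#'
#' @param values numeric matrix, channels in rows, time samples in columns.
#'   A plain numeric vector is treated as a single channel.
#' @param labels character vector of unique channel identifiers; defaults to
#'   `"ch1"`, `"ch2"`, ... when omitted.
#' @param sampling_rate samples per second, or `NULL` if unknown. Only used
#'   to convert realigned pattern times into milliseconds.
#'
#' @return An object of class `ts_set`: a list with elements `values`,
#'   `labels` and `sampling_rate`.
#' @examples
#' x <- ts_set(matrix(rnorm(200), nrow = 2), labels = c("Cz", "Pz"))
#' x
#' @export
ts_set <- function(values, labels = NULL, sampling_rate = NULL) {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, nrow = 1)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels in rows)", call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("need at least 1 channel and 2 time samples", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(values))) rownames(values) else paste0("ch", seq_len(nrow(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("`labels` length (", length(labels), ") != number of channels (",
         nrow(values), ")", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("channel labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(sampling_rate)) {
    stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1, sampling_rate > 0)
  }
  rownames(values) <- labels
  structure(
    list(values = values, labels = labels, sampling_rate = sampling_rate),
    class = "ts_set"
  )
}

#' Coerce a tidy data frame to a `ts_set`
#'
#' Expects one row per (channel, time) observation in long format.
#'
#' @param x data frame with columns named by `channel`, `time` and `value`.
#' @param channel,time,value column names (strings).
#' @param sampling_rate passed through to [ts_set()].
#' @return A `ts_set`.
#' @examples
#' df <- tidyr::expand_grid(channel = c("a", "b"), time = 1:50)
#' df$value <- rnorm(nrow(df))
#' as_ts_set(df)
#' @export
as_ts_set <- function(x, channel = "channel", time = "time", value = "value",
                      sampling_rate = NULL) {
  stopifnot(is.data.frame(x), all(c(channel, time, value) %in% names(x)))
  wide <- tidyr::pivot_wider(
    dplyr::arrange(x, .data[[channel]], .data[[time]]),
    id_cols = dplyr::all_of(channel),
    names_from = dplyr::all_of(time),
    values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) stop("channels do not share a complete time grid", call. = FALSE)
  ts_set(m, labels = wide[[1]], sampling_rate = sampling_rate)
}

#' @export
print.ts_set <- function(x, ...) {
  cat("<ts_set> ", nrow(x$values), " channel(s) x ", ncol(x$values), " samples",
      if (!is.null(x$sampling_rate)) paste0(" @ ", x$sampling_rate, " Hz"), "\n", sep = "")
  cat("channels: ", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname ts_set
n_channels <- function(values) UseMethod("n_channels")

#' @export
n_channels.ts_set <- function(values) nrow(values$values)

#' Tidy a `ts_set` into a long tibble
#'
#' @param x a `ts_set`.
#' @param ... unused.
#' @return Tibble with columns `channel`, `time` (sample index, 1-based) and
#'   `value`.
#' @method tidy ts_set
#' @export
tidy.ts_set <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$labels, each = ncol(x$values)),
    time = rep(seq_len(ncol(x$values)), times = nrow(x$values)),
    value = as.vector(t(x$values))
  )
}
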