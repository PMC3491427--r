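#' Adjacency matrix from one time-slice of symbols
#'
#' Two channels are functionally connected at a time point exactly when their
#' order-pattern symbols are identical. The resulting graph is always a
#' disjoint union of cliques (one clique per symbol value present), since
#' symbol identity is an equivalence relation. Self-links are excluded.
#'
#' @param symbols_at_t integer vector of N >= 2 symbols, one per channel.
#' @return N x N symmetric 0/1 matrix with zero diagonal.
#' @examples
#' adjacency_at(c(5, 5, 2, 5, 7)) # 3-clique on channels 1, 2, 4
#' @export
adjacency_at <- function(symbols_at_t) {
  n <- length(symbols_at_t)
  if (n < 2) stop("need at least 2 channels", call. = FALSE)
  A <- outer(symbols_at_t, symbols_at_t, "==") * 1L
  diag(A) <- 0L
  A
}

#' Build the temporal network sequence from symbol sequences
#'
#' Takes the aligned per-channel symbol sequences and represents the network
#' at every symbol time point. Internally channels are grouped by symbol (the
#' dense matrix is a view, available via [adjacency_matrices()]); since each
#' network is a union of cliques, the symbol vector determines the graph
#' exactly. Timestamps are realigned to the pattern-window centres with
#' [realign_times()] using the dimension the symbols were built with.
#'
#' @param symbols an `op_symbols` object from [symbolize_set()], covering at
#'   least 2 channels.
#' @param sampling_rate optional samples/second; when given (or carried by
#'   `symbols`), realigned times are in milliseconds.
#' @return An `op_networks` object: list with `symbols` (L x N integer
#'   matrix), `times` (realigned, fractional), `labels`, `d`, `tau`,
#'   `time_unit` ("samples" or "ms").
#' @examples
#' x <- ts_set(matrix(rnorm(300), nrow = 3))
#' nets <- build_network_sequence(symbolize_set(x, d = 3, tau = 2))
#' length(nets$times)
#' @export
build_network_sequence <- function(symbols, sampling_rate = NULL) {
  stopifnot(inherits(symbols, "op_symbols"))
  if (ncol(symbols$symbols) < 2) stop("need at least 2 channels", call. = FALSE)
  if (is.null(sampling_rate)) sampling_rate <- symbols$sampling_rate
  anchors <- seq_len(nrow(symbols$symbols)) + symbols$start_index - 1L
  times <- realign_times(anchors, list(d = symbols$d, tau = symbols$tau),
                         sampling_rate = sampling_rate)
  structure(
    list(symbols = symbols$symbols, times = times, labels = symbols$labels,
         d = symbols$d, tau = symbols$tau,
         time_unit = if (is.null(sampling_rate)) "samples" else "ms"),
    class = "op_networks"
  )
}

#' @export
print.op_networks <- function(x, ...) {
  cat("<op_networks> ", length(x$times), " networks on ", length(x$labels),
      " nodes (d = ", x$d, ", tau = ", x$tau, "); times in ", x$time_unit,
      "\n", sep = "")
  invisible(x)
}

#' Materialize dense adjacency matrices
#'
#' @param nets an `op_networks` object.
#' @param which integer indices of the time points wanted (default: all).
#' @return List of N x N symmetric 0/1 matrices.
#' @export
adjacency_matrices <- function(nets, which = seq_along(nets$times)) {
  stopifnot(inherits(nets, "op_networks"))
  lapply(which, function(i) {
    A <- adjacency_at(nets$symbols[i, ])
    dimnames(A) <- list(nets$labels, nets$labels)
    A
  })
}

#' Tidy a network sequence into a long edge list
#'
#' The canonical interchange format: one row per undirected link per time
#' point, with `from < to` as channel indices and realigned timestamps.
#'
#' @param x an `op_networks` object.
#' @param ... unused.
#' @return Tibble with columns `t` (network index), `time` (realigned),
#'   `from`, `to` (1-based channel indices, `from < to`), `from_label`,
#'   `to_label`.
#' @method tidy op_networks
#' @export
tidy.op_networks <- function(x, ...) {
  rows <- purrr::map(seq_along(x$times), function(i) {
    s <- x$symbols[i, ]
    # pairs within each symbol class
    cls <- split(seq_along(s), s)
    cls <- cls[lengths(cls) > 1]
    if (length(cls) == 0) return(NULL)
    prs <- purrr::map(cls, function(idx) {
      cmb <- utils::combn(idx, 2)
      tibble::tibble(from = cmb[1, ], to = cmb[2, ])
    })
    dplyr::bind_rows(prs) |>
      dplyr::mutate(t = i, time = x$times[i], .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(t = integer(), time = numeric(),
                          from = integer(), to = integer())
  }
  out$from_label <- x$labels[out$from]
  out$to_label <- x$labels[out$to]
  dplyr::arrange(out, t, from, to)
}

#' Export one network of the sequence as GraphML
#'
#' @param nets an `op_networks` object.
#' @param index which time point to export.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(nets, index, path) {
  stopifnot(inherits(nets, "op_networks"),
            index >= 1, index <= length(nets$times))
  A <- adjacency_matrices(nets, index)[[1]]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
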