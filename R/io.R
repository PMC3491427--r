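#' Read a delimited multichannel time-series matrix
#'
#' Reads CSV/TSV text with one row per channel (or per sample with
#' `orientation = "samples"`), an optional first header row of channel
#' labels, and numeric cells everywhere else. Ragged rows and non-numeric
#' cells are reported with their line and column numbers.
#'
#' @param path file path.
#' @param orientation `"channels"` (rows are channels, default) or
#'   `"samples"` (rows are time samples; the matrix is transposed on read).
#' @param delimiter field separator; default inferred from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @param header `TRUE`/`FALSE`, or `NULL` (default) to auto-detect: a first
#'   line containing any non-numeric token is treated as the label row. For
#'   channel-major files the header lists one label per data row; for
#'   sample-major files one label per column.
#' @param sampling_rate optional samples/second stored on the result.
#' @return A [ts_set()].
#' @export
read_timeseries <- function(path, orientation = c("channels", "samples"),
                            delimiter = NULL, header = NULL,
                            sampling_rate = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  cells <- lapply(lines, function(l) trimws(strsplit(l, delimiter, fixed = TRUE)[[1]]))
  first_numeric <- suppressWarnings(as.numeric(cells[[1]]))
  if (is.null(header)) header <- anyNA(first_numeric)
  labels <- NULL
  offset <- 0L
  if (header) {
    labels <- cells[[1]]
    cells <- cells[-1]
    offset <- 1L
    if (length(cells) == 0) stop("file contains only a header row", call. = FALSE)
  }
  widths <- lengths(cells)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])
    stop("ragged rows in ", path, ": line(s) ",
         paste(utils::head(bad + offset, 5), collapse = ", "), " have ",
         paste(utils::head(widths[bad], 5), collapse = ", "),
         " fields, expected ", widths[1], call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(cells), ncol = widths[1])
  for (i in seq_along(cells)) {
    row <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(row)) {
      col <- which(is.na(row))[1]
      stop("non-numeric cell at line ", i + offset, ", column ", col,
           ": '", cells[[i]][col], "'", call. = FALSE)
    }
    m[i, ] <- row
  }
  if (orientation == "samples") m <- t(m)
  # after orientation is normalized, rows are channels; the header (if any)
  # must supply one label per channel
  if (!is.null(labels) && length(labels) != nrow(m)) {
    stop("header has ", length(labels), " label(s) but the file has ",
         nrow(m), " channel(s) under orientation = '", orientation, "'",
         call. = FALSE)
  }
  ts_set(m, labels = labels, sampling_rate = sampling_rate)
}

#' Write / read a network sequence as an edge list
#'
#' The canonical interchange format: a TSV with one row per undirected link
#' per time point (`t`, `time`, `from`, `to`) plus a JSON sidecar
#' (`<path>.json`) recording labels, realigned times, `d`, `tau` and the
#' number of networks, so the full adjacency sequence round-trips exactly
#' even through empty networks.
#'
#' @param nets an `op_networks` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(nets, path) {
  stopifnot(inherits(nets, "op_networks"))
  edges <- tidy.op_networks(nets)
  utils::write.table(edges[, c("t", "time", "from", "to")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(labels = nets$labels, times = nets$times, d = nets$d,
               tau = nets$tau, n_networks = length(nets$times),
               time_unit = nets$time_unit)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list()`: an `op_networks` object whose adjacency
#'   matrices equal those written (component labels stand in for the original
#'   symbols, which the edge list does not determine).
#' @export
read_edge_list <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- utils::read.table(path, sep = "\t", header = TRUE)
  n <- length(meta$labels)
  L <- meta$n_networks
  symbols <- matrix(0L, nrow = L, ncol = n)
  for (i in seq_len(L)) {
    A <- matrix(0L, n, n)
    e <- edges[edges$t == i, , drop = FALSE]
    if (nrow(e) > 0) {
      A[cbind(e$from, e$to)] <- 1L
      A[cbind(e$to, e$from)] <- 1L
    }
    symbols[i, ] <- graph_components(A)$membership
  }
  colnames(symbols) <- meta$labels
  structure(
    list(symbols = symbols, times = meta$times, labels = meta$labels,
         d = meta$d, tau = meta$tau, time_unit = meta$time_unit),
    class = "op_networks"
  )
}

#' Write the standard output set of a pipeline run
#'
#' Writes the edge list (+ JSON sidecar), the tidy metric table and a JSON
#' run manifest (embedding parameters, seed, package version, timestamp)
#' under deterministic names in `outdir`. Nothing is written if the network
#' sequence is empty.
#'
#' @param nets an `op_networks` object.
#' @param metrics tibble from [metric_time_series()] (or `NULL`).
#' @param outdir output directory, created if missing.
#' @param params optional `embedding_params` recorded in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(nets, metrics = NULL, outdir, params = NULL,
                          seed = NULL) {
  stopifnot(inherits(nets, "op_networks"))
  if (length(nets$times) == 0) stop("empty network sequence; nothing written", call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c(edges = file.path(outdir, "edges.tsv"))
  write_edge_list(nets, files[["edges"]])
  if (!is.null(metrics)) {
    files[["metrics"]] <- file.path(outdir, "metrics.tsv")
    utils::write.table(metrics, files[["metrics"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package = "opnet",
    version = as.character(utils::packageVersion("opnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_channels = length(nets$labels),
    n_networks = length(nets$times),
    d = nets$d, tau = nets$tau, time_unit = nets$time_unit,
    seed = seed,
    params = if (!is.null(params)) {
      list(d = params$d, d_hat = params$d_hat, tau = params$tau,
           span = params$span, per_channel_d = params$per_channel_d,
           per_channel_tau = params$per_channel_tau)
    }
  )
  files[["manifest"]] <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}
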