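#' Link density of a binary network
#'
#' Fraction of realized links over the `N(N-1)` ordered node pairs
#' (self-links excluded), so the empty graph scores 0 and the complete graph
#' 1. For an undirected adjacency matrix this equals the matrix sum divided
#' by `N(N-1)`.
#'
#' @param A symmetric 0/1 adjacency matrix with zero diagonal, N >= 2.
#' @return Density in `[0, 1]`.
#' @examples
#' link_density(adjacency_at(c(5, 5, 2, 5, 7))) # 6/20 = 0.3
#' @export
link_density <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}

check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("`A` must be square", call. = FALSE)
  if (nrow(A) < 2) stop("need at least 2 nodes", call. = FALSE)
  invisible(TRUE)
}

#' Clustering coefficients of a binary network
#'
#' The clustering of node i is the density of links among its neighbours:
#' `C_i = 2 E_i / (k_i (k_i - 1))` with `E_i` the number of (unordered) links
#' among the `k_i` neighbours. Nodes of degree < 2 are assigned `C_i = 0` and
#' kept in the network average `C = mean(C_i)`; this convention makes `C`
#' grow with link density while the normalized clustering `C' = C / rho`
#' (deviation from the density expected by chance) falls — the behaviour seen
#' in order-pattern networks, where every component is a clique and all
#' defined `C_i` equal 1.
#'
#' @inheritParams link_density
#' @return List with `local` (per-node `C_i`), `global` (`C`), `normalized`
#'   (`C' = C / rho`; `NA` when the density is 0).
#' @examples
#' clustering(adjacency_at(c(1, 1, 1, 2, 2)))$global # (3*1 + 2*0)/5 = 0.6
#' @export
clustering <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  k <- rowSums(A)
  local <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] == 1)
    e_i <- sum(A[nb, nb]) / 2
    local[i] <- 2 * e_i / (k[i] * (k[i] - 1))
  }
  rho <- link_density(A)
  glob <- mean(local)
  list(local = local, global = glob,
       normalized = if (rho > 0) glob / rho else NA_real_)
}

#' Connected components of a binary network
#'
#' Maximal connected subgraphs by breadth-first traversal; singletons count
#' as components of size 1 (so a fully segregated network of N nodes has N
#' components). In order-pattern networks the component count equals the
#' number of distinct symbols among the channels.
#'
#' @inheritParams link_density
#' @return List with `count`, `membership` (integer label per node, 1-based
#'   in discovery order) and `sizes`.
#' @export
graph_components <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  membership <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (membership[s] > 0) next
    comp <- comp + 1L
    queue <- s
    membership[s] <- comp
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] == 1 & membership == 0L)
      membership[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  list(count = comp, membership = membership,
       sizes = as.integer(tabulate(membership, nbins = comp)))
}

#' Shortest-path distance between two nodes
#'
#' Breadth-first search on the binary network. Returns 0 for `i == j`, the
#' minimal number of links crossed otherwise, and `Inf` when the nodes lie in
#' different components. In order-pattern networks every component is a
#' clique, so distances are always 0, 1 or `Inf`; the implementation is
#' nevertheless generic.
#'
#' @inheritParams link_density
#' @param i,j node indices (1-based).
#' @return Non-negative integer distance, or `Inf`.
#' @export
shortest_path_distance <- function(A, i, j) {
  check_adjacency(A)
  n <- nrow(A)
  stopifnot(i >= 1, i <= n, j >= 1, j <= n)
  if (i == j) return(0)
  dist <- rep(Inf, n)
  dist[i] <- 0
  queue <- i
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] == 1 & is.infinite(dist))
    dist[nb] <- dist[v] + 1
    if (is.finite(dist[j])) return(dist[j])
    queue <- c(queue, nb)
  }
  Inf
}

op_metric_names <- c("density", "clustering", "norm_clustering",
                     "n_components", "mean_component_size",
                     "largest_component")

# fast per-time metrics from the symbol partition: every network is a union
# of cliques, so class sizes n_s determine everything.
metrics_from_classes <- function(sizes, n) {
  links2 <- sum(sizes * (sizes - 1))            # ordered pair count
  rho <- links2 / (n * (n - 1))
  c_global <- sum(sizes[sizes >= 3]) / n        # C_i = 1 iff class size >= 3
  c(density = rho,
    clustering = c_global,
    norm_clustering = if (rho > 0) c_global / rho else NA_real_,
    n_components = length(sizes),
    mean_component_size = mean(sizes),
    largest_component = max(sizes))
}

#' Time-resolved graph metrics of a network sequence
#'
#' Evaluates the selected graph measures at every network time point and
#' returns them in tidy long format. Exploits the clique structure of
#' order-pattern networks (symbol-class sizes determine every metric), which
#' is verified against the generic adjacency-matrix implementations in the
#' package tests.
#'
#' @param nets an `op_networks` object.
#' @param metrics character vector from `"density"`, `"clustering"`,
#'   `"norm_clustering"`, `"n_components"`, `"mean_component_size"`,
#'   `"largest_component"`.
#' @return Tibble with columns `t` (network index), `time` (realigned),
#'   `metric`, `value`. Normalized clustering is `NA` where the density is 0.
#' @examples
#' x <- ts_set(matrix(rnorm(500), nrow = 5))
#' nets <- build_network_sequence(symbolize_set(x, d = 3, tau = 3))
#' metric_time_series(nets, c("density", "n_components"))
#' @export
metric_time_series <- function(nets, metrics = c("density", "norm_clustering",
                                                 "n_components")) {
  stopifnot(inherits(nets, "op_networks"), length(nets$times) > 0)
  unknown <- setdiff(metrics, op_metric_names)
  if (length(unknown) > 0) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(op_metric_names, collapse = ", "), call. = FALSE)
  }
  n <- length(nets$labels)
  vals <- vapply(seq_along(nets$times), function(i) {
    sizes <- as.integer(table(nets$symbols[i, ]))
    metrics_from_classes(sizes, n)
  }, numeric(length(op_metric_names)))
  rownames(vals) <- op_metric_names
  tibble::tibble(
    t = rep(seq_along(nets$times), times = length(metrics)),
    time = rep(nets$times, times = length(metrics)),
    metric = rep(metrics, each = length(nets$times)),
    value = as.vector(t(vals[metrics, , drop = FALSE]))
  )
}

#' Plot time-resolved network metrics
#'
#' One panel per metric against the realigned time axis.
#'
#' @param x tibble from [metric_time_series()] (columns `time`, `metric`,
#'   `value`), optionally with a `condition` column mapped to colour.
#' @return A ggplot object.
#' @export
plot_metric_series <- function(x) {
  stopifnot(all(c("time", "metric", "value") %in% names(x)))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$time, y = .data$value))
  if ("condition" %in% names(x)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$condition))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (realigned)", y = NULL)
}
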