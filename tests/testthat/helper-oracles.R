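# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# with the package implementations.

# all permutations of 1:d in lexicographic order, one per row
oracle_perms <- function(d) {
  if (d == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(d - 1)
  out <- matrix(0L, nrow = factorial(d), ncol = d)
  row <- 1
  for (first in seq_len(d)) {
    rest <- setdiff(seq_len(d), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

# brute-force all-pairs adjacency from a symbol vector
oracle_adjacency <- function(symbols) {
  n <- length(symbols)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && symbols[i] == symbols[j]) A[i, j] <- 1L
    }
  }
  A
}

# component count by repeated reachability expansion (no BFS code shared)
oracle_component_count <- function(A) {
  n <- nrow(A)
  reach <- A == 1 | diag(n) == 1
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  nrow(unique(reach))
}

# exhaustive paired sign-flip p-value (two-sided, |mean| statistic)
oracle_exhaustive_p <- function(d) {
  n <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_stats <- abs(signs %*% d) / n
  mean(null_stats >= obs - 1e-12)
}

# literal 2-D histogram mutual information in bits
oracle_mi <- function(u, lag, n_bins) {
  n <- length(u) - lag
  a <- u[1:n]; b <- u[(1 + lag):(lag + n)]
  cut_a <- cut(a, breaks = seq(min(a), max(a), length.out = n_bins + 1),
               include.lowest = TRUE)
  cut_b <- cut(b, breaks = seq(min(b), max(b), length.out = n_bins + 1),
               include.lowest = TRUE)
  joint <- table(cut_a, cut_b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  total <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      if (joint[i, j] > 0) {
        total <- total + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
      }
    }
  }
  as.numeric(total)
}

# shared small Lorenz fixtures (computed once per test run)
lorenz_pair_cache <- new.env()
lorenz_pair <- function(g, seed, transient = 10000, length = 1000) {
  key <- paste(g, seed, transient, length, sep = "_")
  if (is.null(lorenz_pair_cache[[key]])) {
    lorenz_pair_cache[[key]] <- simulate_coupled_lorenz(
      lorenz_config(g = g, transient = transient, length = length, seed = seed))
  }
  lorenz_pair_cache[[key]]
}
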