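#' Paired sign-flip permutation test at a single time point
#'
#' Two-sided non-parametric counterpart of a paired t-test. For per-subject
#' condition values `a` and `b` the differences `d_s = a_s - b_s` are formed;
#' the statistic is `|mean(d)|`, and the null distribution is obtained by
#' randomly flipping the sign of each subject's difference (exchangeability
#' within subject under the null). The add-one estimator
#' `p = (1 + #{permutations with |mean| >= observed}) / (n_perm + 1)` keeps
#' `p >= 1/(n_perm + 1)` and never reports an impossible 0.
#'
#' @param a,b numeric vectors of equal length (one value per subject).
#' @param n_perm number of random sign assignments (default 2000).
#' @param seed optional integer seed for reproducibility.
#' @return p-value in `(0, 1]`, with attribute `statistic` (the observed
#'   `|mean(d)|`).
#' @examples
#' permutation_test_scalar(rnorm(9), rnorm(9), n_perm = 500, seed = 1)
#' @export
permutation_test_scalar <- function(a, b, n_perm = 2000, seed = NULL) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired (equal length)", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- a - b
  obs <- abs(mean(d))
  if (all(d == 0)) return(structure(1, statistic = 0))
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
  null_stat <- abs(signs %*% d) / n
  p <- (1 + sum(null_stat >= obs)) / (n_perm + 1)
  structure(p, statistic = obs)
}

#' Sliding permutation test over the time axis
#'
#' Applies [permutation_test_scalar()] at every time point of two aligned
#' subjects-by-time condition panels, under one seeded random stream with
#' independent sign draws per time point. No multiple-testing correction is
#' applied; the conventional 0.05 and 0.01 levels are drawn as reference
#' lines by [autoplot.op_permtest()].
#'
#' @param panel_a,panel_b numeric matrices, subjects in rows and time points
#'   in columns, with rows aligned subject-by-subject across panels.
#' @param times optional time axis (defaults to the column index).
#' @param n_perm permutations per time point (default 2000).
#' @param seed integer seed for the shared random stream.
#' @param statistic name recorded in the result (the test statistic is the
#'   absolute mean paired difference).
#' @return An `op_permtest` tibble with columns `time`, `statistic`, `p`, and
#'   attributes `n_perm`, `seed`, `statistic_name`, `n_subjects`.
#' @export
sliding_permutation_test <- function(panel_a, panel_b, times = NULL,
                                     n_perm = 2000, seed = NULL,
                                     statistic = "abs mean paired difference") {
  panel_a <- as.matrix(panel_a); panel_b <- as.matrix(panel_b)
  if (!all(dim(panel_a) == dim(panel_b))) {
    stop("panels must share subjects and time axis; got ",
         paste(dim(panel_a), collapse = "x"), " vs ",
         paste(dim(panel_b), collapse = "x"), call. = FALSE)
  }
  n_t <- ncol(panel_a)
  if (is.null(times)) times <- seq_len(n_t)
  if (length(times) != n_t) stop("`times` length must match panel columns", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- numeric(n_t)
  stat <- numeric(n_t)
  for (j in seq_len(n_t)) {
    r <- permutation_test_scalar(panel_a[, j], panel_b[, j], n_perm = n_perm,
                                 seed = NULL)  # one shared stream
    p[j] <- as.numeric(r)
    stat[j] <- attr(r, "statistic")
  }
  out <- tibble::new_tibble(
    list(time = as.numeric(times), statistic = stat, p = p),
    nrow = n_t, class = "op_permtest"
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "statistic_name") <- statistic
  attr(out, "n_subjects") <- nrow(panel_a)
  out
}

#' @method tidy op_permtest
#' @export
tidy.op_permtest <- function(x, ...) {
  tibble::as_tibble(unclass_permtest(x))
}

#' @method glance op_permtest
#' @export
glance.op_permtest <- function(x, ...) {
  tibble::tibble(
    n_time = nrow(x),
    n_subjects = attr(x, "n_subjects"),
    n_perm = attr(x, "n_perm"),
    min_p = min(x$p),
    n_below_05 = sum(x$p < 0.05),
    n_below_01 = sum(x$p < 0.01)
  )
}

unclass_permtest <- function(x) {
  class(x) <- setdiff(class(x), "op_permtest")
  x
}

#' Plot a sliding permutation test
#'
#' p-values over time on a log scale with the 0.05 (dash-dotted) and 0.01
#' (dashed) reference levels.
#'
#' @param object an `op_permtest` from [sliding_permutation_test()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot op_permtest
#' @export
autoplot.op_permtest <- function(object, ...) {
  ggplot2::ggplot(tidy.op_permtest(object),
                  ggplot2::aes(x = .data$time, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dotdash") +
    ggplot2::geom_hline(yintercept = 0.01, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "p (uncorrected)")
}
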