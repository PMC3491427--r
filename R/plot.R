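#' Plot symbol sequences as a colour-coded raster
#'
#' Channels on the vertical axis, anchor time on the horizontal, one tile per
#' symbol. Synchronized channels appear as identical colour stripes.
#'
#' @param object an `op_symbols` from [symbolize_set()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot op_symbols
#' @export
autoplot.op_symbols <- function(object, ...) {
  df <- tidy.op_symbols(object)
  df$channel <- factor(df$channel, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$channel,
                                   fill = factor(.data$symbol))) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "anchor sample", y = NULL,
                  fill = paste0("pattern (d = ", object$d, ")")) +
    ggplot2::theme(legend.position = if (factorial(object$d) > 24) "none" else "right")
}
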