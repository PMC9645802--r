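#' Plot a trace set
#'
#' Spaghetti plot of all runs (thin lines) with the ensemble mean overlaid.
#'
#' @param object a [trace_set()].
#' @param max_runs at most this many individual runs are drawn.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
autoplot.trace_set <- function(object, max_runs = 50, ...) {
  nr <- min(nrow(object$traces), max_runs)
  times <- object$t0 + (seq_len(ncol(object$traces)) - 1) * object$dt
  df <- data.frame(
    time_s = rep(times, nr),
    v = as.vector(t(object$traces[seq_len(nr), , drop = FALSE])),
    run = factor(rep(seq_len(nr), each = length(times)))
  )
  mu <- data.frame(time_s = times, v = colMeans(object$traces))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$v)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$run), alpha = 0.2) +
    ggplot2::geom_line(data = mu, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = object$probe)
}

#' Plot a confidence band
#'
#' @param band a [ci_band()] tibble.
#' @return A ggplot object.
#' @export
plot_ci_band <- function(band) {
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "time (s)", y = "mean with CI band")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
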