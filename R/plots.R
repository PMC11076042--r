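#' Plot the firing-rate raster of a simulation
#'
#' Heatmap of rates (neurons x time). Requires ggplot2.
#'
#' @param record A `simulation_record` with rates recorded.
#' @param every Plot every `every`-th step to keep the raster light.
#' @return A ggplot object.
#' @export
plot_rates <- function(record, every = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_rates requires ggplot2")
  if (is.null(record$rates)) stop("record has no rate trace")
  steps <- seq(1, nrow(record$rates), by = every)
  df <- expand.grid(t = steps, neuron = seq_len(ncol(record$rates)))
  df$rate <- as.vector(record$rates[steps, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$neuron,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time step", y = "neuron", fill = "rate")
}

#' Plot a per-day recurrent weight matrix snapshot
#'
#' @param record A `simulation_record`.
#' @param day Day index.
#' @return A ggplot object.
#' @export
plot_weight_snapshot <- function(record, day = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_weight_snapshot requires ggplot2")
  W <- record$W_snapshots[[day]]
  df <- expand.grid(post = seq_len(nrow(W)), pre = seq_len(ncol(W)))
  df$w <- as.vector(W)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pre, y = .data$post,
                                   fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, record$params$c)) +
    ggplot2::labs(title = sprintf("recurrent weights, day %d", day),
                  x = "presynaptic", y = "postsynaptic", fill = "W")
}

#' Plot mean pattern correlation with day 1 across days
#'
#' @param result A `"drift"` `experiment_result`.
#' @return A ggplot object.
#' @export
plot_drift <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_drift requires ggplot2")
  s <- summarize_table(result$tables$correlation_by_day)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$day, y = .data$corr_day1_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$corr_day1_mean - .data$corr_day1_sem,
      ymax = .data$corr_day1_mean + .data$corr_day1_sem)) +
    ggplot2::labs(x = "day", y = "corr with day-1 pattern")
}
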