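#' Plot the prequential-accuracy trace of a run
#'
#' @param object An `onsnn_result`.
#' @param ... Unused.
#' @return A ggplot: prequential accuracy against samples processed, with
#'   the chance level for the observed class set as a dashed reference.
#' @method autoplot onsnn_result
#' @export
autoplot.onsnn_result <- function(object, ...) {
  chance <- 1 / max(1L, nrow(object$confusion))
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$index, y = .data$acc_pre)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "sample", y = "prequential accuracy",
                  title = sprintf("%s run: final accuracy %.3f",
                                  object$mode, object$summary$accuracy)) +
    ggplot2::theme_minimal()
}

#' Raster plot of a spike train
#'
#' @param x A `spike_train`.
#' @param ... Unused.
#' @return A ggplot raster of excitatory (+1) and inhibitory (-1) events.
#' @export
plot_spike_raster <- function(x, ...) {
  ev <- tidy.spike_train(x)
  ev$polarity <- factor(ev$polarity, levels = c(1, -1),
                        labels = c("excitatory", "inhibitory"))
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time, y = .data$channel,
                                   colour = .data$polarity)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_colour_manual(values = c(excitatory = "steelblue",
                                            inhibitory = "black")) +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-channel synaptic fan-out
#'
#' @param fanout A tibble from [channel_fanout()].
#' @return A ggplot of cumulative excitatory and inhibitory weight per
#'   channel.
#' @export
plot_channel_fanout <- function(fanout) {
  long <- tidyr::pivot_longer(fanout, c("excitatory", "inhibitory"),
                              names_to = "kind", values_to = "weight")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$weight,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(excitatory = "steelblue",
                                          inhibitory = "grey20")) +
    ggplot2::labs(x = NULL, y = "cumulative synaptic weight", fill = NULL) +
    ggplot2::theme_minimal()
}
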