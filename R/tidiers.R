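#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an online/batch run into its outcome log
#'
#' @param x An `onsnn_result`.
#' @param ... Unused.
#' @return The per-sample outcome tibble: index, true and predicted labels,
#'   correctness, candidate distance, repository size, spike counts,
#'   structural events and the running prequential accuracy.
#' @method tidy onsnn_result
#' @export
tidy.onsnn_result <- function(x, ...) {
  x$outcomes
}

#' One-row summary of a run
#'
#' @param x An `onsnn_result`.
#' @param ... Unused.
#' @return A one-row tibble: mode, samples seen and scored, final accuracy,
#'   sensitivity, output-neuron count, hidden spike counts and ratio.
#' @method glance onsnn_result
#' @export
glance.onsnn_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    mode = s$mode, n_samples = s$n_samples, n_scored = s$n_scored,
    accuracy = s$accuracy, sensitivity = s$sensitivity,
    n_output_neurons = s$n_output_neurons,
    spikes_received = s$spikes_received,
    spikes_generated = s$spikes_generated,
    spike_ratio = s$spike_ratio
  )
}
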