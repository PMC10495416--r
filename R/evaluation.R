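#' Prequential accuracy
#'
#' Test-then-train evaluation keeps a running mean of instantaneous 0/1
#' correctness, updated incrementally:
#' `acc(t) = acc(t-1) + (c_t - acc(t-1)) / (t - t_init + 1)` with `c_t = 1`
#' for a correct prediction. `prequential_trace()` maps a correctness
#' sequence to the full accuracy trace; `prequential_update()` performs one
#' incremental step.
#'
#' @param correct Logical vector of per-sample correctness, in stream order.
#' @return `prequential_trace()`: a numeric vector the same length as
#'   `correct`; element t is the accuracy after scoring sample t.
#' @export
prequential_trace <- function(correct) {
  correct <- as.logical(correct)
  if (!length(correct)) return(numeric(0))
  acc <- numeric(length(correct))
  a <- 0
  for (t in seq_along(correct)) {
    a <- a + (as.numeric(correct[t]) - a) / t
    acc[t] <- a
  }
  acc
}

#' @rdname prequential_trace
#' @param acc Accuracy after the previous sample (use 0 before the first).
#' @param n_scored Number of samples scored so far including this one.
#' @export
prequential_update <- function(acc, correct, n_scored) {
  acc + (as.numeric(correct) - acc) / n_scored
}

#' Confusion matrix of a prediction log
#'
#' @param truth,predicted Vectors of true and predicted labels.
#' @param classes Optional class set fixing row/column order.
#' @return A square contingency table, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  table(factor(truth, levels = classes),
        factor(predicted, levels = classes),
        dnn = c("truth", "predicted"))
}

#' Sensitivity (true-positive rate) for a designated class
#'
#' `TP / (TP + FN)` for the positive class (in the stress-recognition
#' setting, the stress class). If no samples of that class were scored the
#' rate is undefined and `NA` is returned with a warning.
#'
#' @param confusion A confusion matrix from [confusion_matrix()].
#' @param positive_class Label of the positive class.
#' @return Scalar in \[0, 1\], or `NA` if undefined.
#' @export
class_sensitivity <- function(confusion, positive_class) {
  if (!positive_class %in% rownames(confusion)) {
    stop(sprintf("Class '%s' not present in the confusion matrix.",
                 positive_class), call. = FALSE)
  }
  row <- confusion[positive_class, ]
  total <- sum(row)
  if (total == 0) {
    warning("No samples of the positive class were scored; sensitivity undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  unname(row[positive_class] / total)
}

#' Hidden-layer sparsification ratio
#'
#' Ratio of spikes generated by the hidden layer to spikes received at the
#' hidden layer over a stream. Small values indicate strong temporal
#' sparsification by the STDP + intrinsic-plasticity combination.
#'
#' @param received Count of input spikes delivered to the hidden layer.
#' @param generated Count of spikes the hidden layer emitted.
#' @return Scalar ratio, or `NA` with a warning when `received` is 0.
#' @export
spike_ratio <- function(received, generated) {
  stopifnot(received >= 0, generated >= 0)
  if (received == 0) {
    warning("No spikes received; spike ratio undefined.", call. = FALSE)
    return(NA_real_)
  }
  generated / received
}
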