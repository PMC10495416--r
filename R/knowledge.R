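#' Class-centroid distances in the output repository
#'
#' Each output neuron's weight vector is a numerical representation of one
#' input sample; the per-class mean of those vectors is the class centroid.
#' This reports the Euclidean distance of every non-baseline centroid to
#' the baseline class's centroid (in the stress-recognition setting the
#' neutral class is the natural baseline).
#'
#' @param repo An `output_repository` with at least one neuron per class.
#' @param baseline_class The reference class.
#' @return A tibble with columns `class`, `baseline`, `distance`.
#' @export
class_centroid_distances <- function(repo, baseline_class) {
  cents <- class_centroids(repo)
  if (!baseline_class %in% names(cents)) {
    stop(sprintf("Baseline class '%s' has no neurons in the repository.",
                 baseline_class), call. = FALSE)
  }
  base <- cents[[baseline_class]]
  other <- setdiff(names(cents), baseline_class)
  tibble::tibble(
    class = other,
    baseline = baseline_class,
    distance = unname(vapply(other,
                             function(cl) sqrt(sum((cents[[cl]] - base)^2)),
                             numeric(1)))
  )
}

# per-class mean weight vector
class_centroids <- function(repo) {
  if (nrow(repo) == 0L) stop("Repository is empty.", call. = FALSE)
  split(repo$weights, repo$label) |>
    lapply(function(ws) Reduce(`+`, ws) / length(ws))
}

#' Per-channel synaptic fan-out
#'
#' Cumulative input-to-hidden synaptic weight per input channel: the sum of
#' the positive (excitatory) weights, the sum of the negative (inhibitory)
#' weights, and their net, across the channel's fan-out row. After a stream
#' these summaries capture which channels the unsupervised learning ended
#' up exciting or suppressing.
#'
#' @param W Weight matrix, channels x hidden neurons.
#' @param channel_names Optional channel labels (defaults to rownames).
#' @return A tibble with columns `channel`, `excitatory`, `inhibitory`,
#'   `net`.
#' @export
channel_fanout <- function(W, channel_names = rownames(W)) {
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(W)))
  if (length(channel_names) != nrow(W)) {
    stop("`channel_names` must match the number of weight-matrix rows.",
         call. = FALSE)
  }
  tibble::tibble(
    channel = channel_names,
    excitatory = unname(apply(W, 1L, function(r) sum(r[r > 0]))),
    inhibitory = unname(apply(W, 1L, function(r) sum(r[r < 0]))),
    net = unname(rowSums(W))
  )
}

#' Drift of the initiation neurons over a stream
#'
#' Per initiation neuron, the Euclidean distance between its weight vector
#' at the end of the initiation phase and at stream end. With per-pass
#' updates disabled (the default) initiation weights are frozen and all
#' distances are zero; with updates enabled the distances measure how far
#' the stream dragged each class representation.
#'
#' @param repo_init Repository snapshot at the end of initiation.
#' @param repo_final Repository snapshot at stream end.
#' @return A tibble with columns `id`, `label`, `distance`.
#' @export
initial_vs_final_drift <- function(repo_init, repo_final) {
  init <- repo_init[repo_init$is_initiation, ]
  fin <- repo_final[repo_final$is_initiation, ]
  ids <- init$id
  if (!all(ids %in% fin$id)) {
    stop("Initiation neurons missing from the final snapshot.",
         call. = FALSE)
  }
  j <- match(ids, fin$id)
  tibble::tibble(
    id = ids,
    label = init$label,
    distance = vapply(seq_along(ids), function(k) {
      sqrt(sum((init$weights[[k]] - fin$weights[[j[k]]])^2))
    }, numeric(1))
  )
}

#' Knowledge-extraction report for a trained model
#'
#' Bundles the interpretability analyses: class-centroid distances to a
#' baseline class and per-channel synaptic fan-out.
#'
#' @param result An `onsnn_result`.
#' @param baseline_class Reference class for centroid distances
#'   (default `"neutral"` when present, else the first class).
#' @param channel_names Channel labels for the fan-out table.
#' @return A list of class `knowledge_report` with tibbles
#'   `centroid_distances` and `channel_fanout`.
#' @export
knowledge_report <- function(result, baseline_class = NULL,
                             channel_names = rownames(result$weights)) {
  labels <- unique(result$repository$label)
  if (is.null(baseline_class)) {
    baseline_class <- if ("neutral" %in% labels) "neutral" else labels[1L]
  }
  structure(
    list(
      centroid_distances = class_centroid_distances(result$repository,
                                                    baseline_class),
      channel_fanout = channel_fanout(result$weights, channel_names),
      baseline_class = baseline_class
    ),
    class = "knowledge_report"
  )
}

#' @export
print.knowledge_report <- function(x, ...) {
  cat(sprintf("<knowledge_report> baseline class: %s\n", x$baseline_class))
  cat("centroid distances:\n")
  print(x$centroid_distances)
  cat("channel fan-out:\n")
  print(x$channel_fanout)
  invisible(x)
}

#' @rdname knowledge_report
#' @param report A `knowledge_report`.
#' @param path JSON output path.
#' @export
write_knowledge_json <- function(report, path) {
  jsonlite::write_json(
    list(baseline_class = report$baseline_class,
         centroid_distances = report$centroid_distances,
         channel_fanout = report$channel_fanout),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
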