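#' Rank-order classifier parameters
#'
#' The output layer stores one weight vector over the hidden neurons per
#' output neuron. At creation the vector is initialized by the rank-order
#' rule — the hidden neuron whose first spike arrives earliest gets weight
#' `alpha * mod^0`, the next `alpha * mod^1`, and so on — then a small
#' drift `d` is added for every subsequent time step in which the hidden
#' neuron spikes and subtracted for every step it stays silent (spike-driven
#' synaptic plasticity). Defaults: `alpha = 1`, `mod = 0.8`, `d = 0.001`.
#'
#' @param alpha Learning parameter (scale of the first-rank weight).
#' @param mod Modulation factor in (0, 1].
#' @param d Drift parameter.
#' @return A list of class `ro_params`.
#' @export
ro_params <- function(alpha = 1, mod = 0.8, d = 0.001) {
  stopifnot(alpha > 0, mod > 0, mod <= 1, d >= 0)
  structure(list(alpha = alpha, mod = mod, d = d), class = "ro_params")
}

#' Rank-order candidate vector from a hidden-layer raster
#'
#' Builds the candidate weight vector a new output neuron would receive for
#' the sample: hidden neurons are ranked by the time of their first spike
#' (earliest rank 0, simultaneous first spikes broken by neuron index) and
#' given `alpha * mod^rank`; neurons that never spike get 0. The drift rule
#' then adds `d` for every post-first-spike step with a spike and subtracts
#' `d` for every silent one.
#'
#' @param raster Logical or 0/1 matrix, hidden neurons x timepoints, for one
#'   sample.
#' @param params An [ro_params()].
#' @return Numeric vector of length `nrow(raster)`. If no hidden neuron
#'   spiked at all, an all-zero vector with attribute `empty = TRUE`.
#' @export
rank_order_vector <- function(raster, params = ro_params()) {
  raster <- raster != 0
  n <- nrow(raster)
  n_t <- ncol(raster)
  first <- apply(raster, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  w <- numeric(n)
  spiked <- !is.na(first)
  if (!any(spiked)) {
    attr(w, "empty") <- TRUE
    return(w)
  }
  ord <- order(first[spiked], seq_len(n)[spiked])
  ranks <- integer(sum(spiked))
  ranks[ord] <- seq_along(ord) - 1L
  w[spiked] <- params$alpha * params$mod^ranks
  if (params$d > 0) {
    for (j in which(spiked)) {
      rest <- if (first[j] < n_t) raster[j, (first[j] + 1L):n_t] else logical(0)
      w[j] <- w[j] + params$d * (sum(rest) - sum(!rest))
    }
  }
  w
}

#' Create an empty output repository
#'
#' The evolving classifier starts with no neurons; the first samples of a
#' stream create one labelled neuron each (the initiation set).
#'
#' @return A tibble of class `output_repository` with zero rows and columns
#'   `id`, `label`, `created_at`, `wins_correct`, `wins_wrong`,
#'   `is_initiation`, `weights` (list-column).
#' @export
new_repository <- function() {
  repo <- tibble::tibble(
    id = integer(0), label = character(0), created_at = integer(0),
    wins_correct = integer(0), wins_wrong = integer(0),
    is_initiation = logical(0), weights = list()
  )
  class(repo) <- c("output_repository", class(repo))
  repo
}

#' Classify a candidate vector against the repository
#'
#' Nearest-neighbour by Euclidean distance over the stored output-neuron
#' weight vectors; exact ties are broken in favour of the neuron created
#' earliest (then lowest id).
#'
#' @param candidate Numeric candidate vector (length = hidden neurons).
#' @param repo An `output_repository` with at least one neuron.
#' @return A list with `label`, `distance`, and `winner_id`.
#' @export
classify_candidate <- function(candidate, repo) {
  if (nrow(repo) == 0L) {
    stop("Output repository is empty: the classifier is not initialized.",
         call. = FALSE)
  }
  d <- vapply(repo$weights, function(w) sqrt(sum((w - candidate)^2)),
              numeric(1))
  ord <- order(d, repo$created_at, repo$id)
  win <- ord[1L]
  list(label = repo$label[win], distance = d[win], winner_id = repo$id[win])
}

#' Evolve (append) a labelled output neuron
#'
#' Called for every initiation sample and after every misclassification:
#' the sample's rank-order candidate vector becomes the weight vector of a
#' new output neuron carrying the true label.
#'
#' @param repo An `output_repository`.
#' @param candidate Numeric weight vector.
#' @param label True class label.
#' @param sample_index Stream position at which the neuron is created.
#' @param is_initiation Is this one of the initiation neurons?
#' @return The grown repository.
#' @export
evolve_neuron <- function(repo, candidate, label, sample_index,
                          is_initiation = FALSE) {
  new_id <- if (nrow(repo)) max(repo$id) + 1L else 1L
  row <- tibble::tibble(
    id = new_id, label = as.character(label),
    created_at = as.integer(sample_index),
    wins_correct = 0L, wins_wrong = 0L,
    is_initiation = is_initiation, weights = list(as.numeric(candidate))
  )
  out <- dplyr::bind_rows(repo, row)
  class(out) <- class(repo)
  out
}

#' Eliminate persistently wrong evolved neurons
#'
#' Removes evolved (non-initiation) neurons that have won at least
#' `min_errors` misclassifications and have more wrong wins than correct
#' ones. A class is never emptied: if removal would delete every neuron of
#' some class, the least-offending one (fewest wrong wins, then oldest) is
#' retained.
#'
#' @param repo An `output_repository`.
#' @param min_errors Minimum wrong-win count before a neuron is eligible
#'   for elimination (default 3).
#' @return The (possibly smaller) repository.
#' @export
eliminate_neurons <- function(repo, min_errors = 3) {
  if (nrow(repo) == 0L) return(repo)
  drop <- !repo$is_initiation &
    repo$wins_wrong >= min_errors &
    repo$wins_wrong > repo$wins_correct
  if (any(drop)) {
    for (cl in unique(repo$label)) {
      in_cl <- repo$label == cl
      if (all(drop[in_cl])) {
        keep <- which(in_cl)[order(repo$wins_wrong[in_cl],
                                   repo$created_at[in_cl])][1L]
        drop[keep] <- FALSE
      }
    }
  }
  out <- repo[!drop, , drop = FALSE]
  class(out) <- class(repo)
  out
}

#' Record a classification outcome on the winning neuron
#'
#' @param repo An `output_repository`.
#' @param winner_id Id of the neuron that won the classification.
#' @param correct Was the prediction correct?
#' @return The repository with the winner's counter incremented.
#' @export
record_win <- function(repo, winner_id, correct) {
  i <- match(winner_id, repo$id)
  if (is.na(i)) stop("Unknown winner id.", call. = FALSE)
  if (correct) repo$wins_correct[i] <- repo$wins_correct[i] + 1L
  else repo$wins_wrong[i] <- repo$wins_wrong[i] + 1L
  repo
}

#' Export the repository
#'
#' `tidy()` returns one row per neuron with the weight vector unnested wide
#' (`w1..wN`); `write_repository_csv()`/`write_repository_json()` persist it.
#'
#' @param x An `output_repository`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy output_repository
#' @export
tidy.output_repository <- function(x, ...) {
  meta <- dplyr::select(tibble::as_tibble(x), -"weights")
  if (nrow(x) == 0L) return(meta)
  wmat <- do.call(rbind, x$weights)
  colnames(wmat) <- paste0("w", seq_len(ncol(wmat)))
  dplyr::bind_cols(meta, tibble::as_tibble(wmat))
}

#' @rdname tidy.output_repository
#' @param repo An `output_repository`.
#' @param path Output file path.
#' @export
write_repository_csv <- function(repo, path) {
  utils::write.csv(tidy.output_repository(repo), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tidy.output_repository
#' @export
write_repository_json <- function(repo, path) {
  jsonlite::write_json(
    purrr::pmap(repo, function(id, label, created_at, wins_correct,
                               wins_wrong, is_initiation, weights) {
      list(id = id, label = label, created_at = created_at,
           wins_correct = wins_correct, wins_wrong = wins_wrong,
           is_initiation = is_initiation, weights = weights)
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tidy.output_repository
#' @export
read_repository_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  repo <- new_repository()
  for (nr in x) {
    repo <- dplyr::bind_rows(repo, tibble::tibble(
      id = as.integer(nr$id), label = as.character(nr$label),
      created_at = as.integer(nr$created_at),
      wins_correct = as.integer(nr$wins_correct),
      wins_wrong = as.integer(nr$wins_wrong),
      is_initiation = as.logical(nr$is_initiation),
      weights = list(as.numeric(unlist(nr$weights)))
    ))
  }
  class(repo) <- c("output_repository", class(repo))
  repo
}
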