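#' Construct a multichannel signal segment
#'
#' A segment is the unit the network consumes: a channels-by-timepoints
#' numeric matrix (e.g. 4 EEG channels at 256 Hz for 5 s = 1280 columns)
#' plus its sampling rate and channel labels.
#'
#' @param values Numeric matrix, one row per channel, one column per
#'   time point. At least 2 time points are required.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector of unique channel labels; defaults
#'   to the matrix rownames, or `ch1..chK` when absent.
#'
#' @return An object of class `eeg_segment`.
#' @export
#' @examples
#' seg <- eeg_segment(matrix(sin(seq(0, 10, length.out = 64)), nrow = 1),
#'                    sampling_rate = 256)
eeg_segment <- function(values, sampling_rate = 256, channel_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels x timepoints).",
         call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("A segment needs at least 2 time points.", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(values)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(nrow(values)))
    }
  }
  if (length(channel_names) != nrow(values) || anyDuplicated(channel_names)) {
    stop("`channel_names` must be unique and match the number of rows.",
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number.", call. = FALSE)
  }
  rownames(values) <- channel_names
  structure(
    list(values = values,
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channel(s) x %d timepoints @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$sampling_rate))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_segment <- function(x) dim(x$values)

#' Temporal differences of a segment
#'
#' First differences along time, per channel: element (c, t) is
#' x[c, t+1] - x[c, t]. This is the quantity the address event
#' representation (AER) thresholds.
#'
#' @param segment An [eeg_segment()].
#' @return Numeric matrix, channels x (timepoints - 1).
#' @export
temporal_difference <- function(segment) {
  stopifnot(inherits(segment, "eeg_segment"))
  v <- segment$values
  d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  rownames(d) <- segment$channel_names
  d
}

#' Adaptive AER spike threshold for one channel
#'
#' The per-channel, per-segment threshold is `mean(td) + f * sd_pop(td)`
#' where `td` are the channel's temporal differences over the whole segment
#' and `sd_pop` is the population (uncorrected) standard deviation. The
#' threshold factor `f` controls sparseness: larger `f`, fewer spikes.
#'
#' @param tempdiff Non-empty numeric vector of temporal differences.
#' @param f Non-negative threshold factor (default 0.7).
#' @return Scalar threshold.
#' @export
aer_threshold <- function(tempdiff, f = 0.7) {
  if (length(tempdiff) == 0L) {
    stop("`tempdiff` must be non-empty.", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || f < 0) {
    stop("`f` must be a single non-negative number.", call. = FALSE)
  }
  mean(tempdiff) + f * sd_pop(tempdiff)
}

# population (n-denominator) standard deviation; AER uses no Bessel correction
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Encode a segment into a ternary spike train (AER)
#'
#' Address event representation with a symmetric adaptive threshold:
#' per channel, time step t >= 2 emits +1 (excitatory) if the temporal
#' difference exceeds the channel threshold, -1 (inhibitory) if it falls
#' below its negation, and 0 otherwise. The first time step has no
#' predecessor and emits 0. Comparisons are strict, so a difference exactly
#' at the threshold stays silent.
#'
#' @inheritParams temporal_difference
#' @param f Threshold factor, see [aer_threshold()].
#' @return An integer matrix of class `spike_train`, same shape as the
#'   segment, entries in {-1, 0, 1}.
#' @export
#' @examples
#' seg <- eeg_segment(matrix(c(0, 1, 0, 1), nrow = 1))
#' aer_encode(seg, f = 0.7)
aer_encode <- function(segment, f = 0.7) {
  td <- temporal_difference(segment)
  thr <- apply(td, 1L, aer_threshold, f = f)
  events <- matrix(0L, nrow = nrow(td), ncol = ncol(td) + 1L,
                   dimnames = list(segment$channel_names, NULL))
  pos <- td > thr
  neg <- td < -thr
  events[, -1L][pos] <- 1L
  events[, -1L][neg] <- -1L
  structure(events, class = c("spike_train", class(events)))
}

#' @export
print.spike_train <- function(x, ...) {
  nz <- sum(x != 0L)
  cat(sprintf("<spike_train> %d channel(s) x %d steps, %d events (%.1f%% of steps)\n",
              nrow(x), ncol(x), nz, 100 * nz / length(x)))
  invisible(x)
}

#' Tidy a spike train into an event table
#'
#' @param x A `spike_train`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time`, `polarity` holding only
#'   the nonzero events.
#' @method tidy spike_train
#' @export
tidy.spike_train <- function(x, ...) {
  idx <- which(unclass(x) != 0L, arr.ind = TRUE)
  chn <- rownames(x)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(x)))
  tibble::tibble(
    channel = chn[idx[, 1L]],
    time = as.integer(idx[, 2L]),
    polarity = as.integer(x[idx])
  ) |> dplyr::arrange(.data$time, .data$channel)
}
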