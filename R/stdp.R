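#' STDP parameters
#'
#' Exponential-window spike-timing-dependent plasticity on the
#' input-to-hidden synapses. Long-term potentiation applies when the
#' post-synaptic spike follows the pre-synaptic one (positive timing
#' difference), depression when it precedes it. Defaults:
#' `A_plus = A_minus = 0.001`, `tau_pos = tau_neg = 10` steps, weight
#' bounds `[-0.5, 0.5]`. Pairs further apart than `pair_window` steps
#' (default `5 * max(tau_pos, tau_neg)`, beyond which the kernel is below
#' `exp(-5)` of its peak) contribute nothing.
#'
#' @param A_plus Maximum potentiation per pair.
#' @param A_minus Maximum depression per pair.
#' @param tau_pos LTP time constant (steps).
#' @param tau_neg LTD time constant (steps).
#' @param w_max,w_min Weight bounds.
#' @param pair_window Pairing cutoff (steps).
#' @return A list of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.001, A_minus = 0.001,
                        tau_pos = 10, tau_neg = 10,
                        w_max = 0.5, w_min = -0.5,
                        pair_window = 5 * max(tau_pos, tau_neg)) {
  stopifnot(w_min < w_max, tau_pos > 0, tau_neg > 0, pair_window > 0,
            A_plus >= 0, A_minus >= 0)
  structure(
    list(A_plus = A_plus, A_minus = A_minus, tau_pos = tau_pos,
         tau_neg = tau_neg, w_max = w_max, w_min = w_min,
         pair_window = pair_window),
    class = "stdp_params"
  )
}

#' Initialize the input-to-hidden synaptic matrix
#'
#' Weights are drawn from a zero-mean Gaussian (sd `sigma`) and clipped to
#' the STDP bounds; both excitatory (positive) and inhibitory (negative)
#' synapses arise from the sign of the draw. Reproducible from `seed`.
#'
#' @param n_inputs Number of input channels.
#' @param n_hidden Number of hidden neurons.
#' @param seed Integer seed.
#' @param sigma Gaussian sd of the initial weights (default 0.1).
#' @param params An [stdp_params()] supplying the clip bounds.
#' @return Numeric matrix, `n_inputs` x `n_hidden`.
#' @export
init_weights <- function(n_inputs, n_hidden, seed, sigma = 0.1,
                         params = stdp_params()) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, sigma >= 0)
  W <- local_seed(seed, {
    matrix(stats::rnorm(n_inputs * n_hidden, mean = 0, sd = sigma),
           nrow = n_inputs, ncol = n_hidden)
  })
  pmin(pmax(W, params$w_min), params$w_max)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' STDP kernel for one pre/post spike pair
#'
#' For timing difference `delta_t = t_post - t_pre` (in steps):
#' `A_plus * exp(-delta_t / tau_pos)` when positive (potentiation),
#' `-A_minus * exp(delta_t / tau_neg)` when negative (depression), and 0
#' for coincident spikes or pairs beyond the pairing window. Vectorized
#' over `delta_t`.
#'
#' @param delta_t Signed timing difference(s), post minus pre.
#' @param params An [stdp_params()].
#' @return Numeric weight change(s).
#' @export
stdp_pair_delta <- function(delta_t, params = stdp_params()) {
  out <- numeric(length(delta_t))
  pos <- delta_t > 0 & delta_t <= params$pair_window
  neg <- delta_t < 0 & delta_t >= -params$pair_window
  out[pos] <- params$A_plus * exp(-delta_t[pos] / params$tau_pos)
  out[neg] <- -params$A_minus * exp(delta_t[neg] / params$tau_neg)
  out
}

#' Apply cumulative STDP to the synaptic matrix
#'
#' The per-synapse weight change is the sum of the pair kernel over every
#' (pre spike time, post spike time) combination within the pairing window,
#' accumulated over the whole sample and applied once at sample end, then
#' clipped to the bounds. Pre-synaptic events of either polarity count as
#' spikes for timing purposes; polarity enters the dynamics only through
#' the input current.
#'
#' @param W Weight matrix, channels x hidden neurons.
#' @param pre_events A `spike_train` (channels x timepoints).
#' @param post_raster Logical or 0/1 matrix (hidden neurons x timepoints).
#' @param params An [stdp_params()].
#' @return The updated, clipped weight matrix.
#' @export
stdp_apply <- function(W, pre_events, post_raster, params = stdp_params()) {
  if (ncol(pre_events) != ncol(post_raster)) {
    stop("Pre and post rasters must cover the same time window.",
         call. = FALSE)
  }
  stopifnot(nrow(W) == nrow(pre_events), ncol(W) == nrow(post_raster))
  post_idx <- which(post_raster != 0, arr.ind = TRUE)   # (neuron, time)
  if (nrow(post_idx) > 0L) {
    post_t <- post_idx[, 2L]
    post_j <- post_idx[, 1L]
    for (i in seq_len(nrow(W))) {
      pre_t <- which(pre_events[i, ] != 0L)
      if (length(pre_t) == 0L) next
      # all (post, pre) timing differences for channel i at once
      dts <- outer(post_t, pre_t, `-`)
      fv <- stdp_pair_delta(as.vector(dts), params)
      dW <- rowsum(rowSums(matrix(fv, nrow = length(post_t))),
                   group = post_j, reorder = FALSE)
      W[i, as.integer(rownames(dW))] <- W[i, as.integer(rownames(dW))] + dW[, 1L]
    }
  }
  pmin(pmax(W, params$w_min), params$w_max)
}

#' Self-prune low-firing hidden neurons
#'
#' Error-triggered soft pruning: every neuron whose spike count over the
#' just-processed sample falls below `sp_thresh` has its threshold raised
#' to the current population maximum, silencing it until intrinsic
#' plasticity decays the threshold back down. Weights are untouched and
#' the neuron stays in the network.
#'
#' @param pop A [lif_population()].
#' @param spike_counts Integer vector of per-neuron spike counts for the
#'   sample just processed.
#' @param sp_thresh Minimum spike count to escape pruning (default 1).
#' @return The updated population.
#' @export
self_prune <- function(pop, spike_counts, sp_thresh = 1) {
  stopifnot(length(spike_counts) == pop$n, sp_thresh >= 0)
  low <- spike_counts < sp_thresh
  if (any(low)) {
    pop$v_thr[low] <- max(pop$v_thr)
  }
  pop
}

#' Export a weight matrix as a tidy table or CSV
#'
#' @param W Weight matrix, channels x hidden neurons.
#' @param channel_names Optional channel labels for the rows.
#' @return A tibble with one row per synapse: `channel`, `hidden`, `weight`.
#' @export
tidy_weights <- function(W, channel_names = rownames(W)) {
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(W)))
  tibble::tibble(
    channel = rep(channel_names, times = ncol(W)),
    hidden = rep(seq_len(ncol(W)), each = nrow(W)),
    weight = as.vector(W)
  )
}

#' @rdname tidy_weights
#' @param path CSV path; rows are channels, columns hidden neurons.
#' @export
write_weights_csv <- function(W, path, channel_names = rownames(W)) {
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(W)))
  df <- data.frame(channel = channel_names, W, check.names = FALSE)
  colnames(df) <- c("channel", paste0("h", seq_len(ncol(W))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
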