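#' Full network configuration
#'
#' Collects every hyperparameter of the three-layer network under its
#' standard defaults: AER threshold factor `f = 0.7`; LIF
#' `v_thresh = 0.05`, `v_rest = 0`, `R = 1`, `C = 10`; STDP
#' `A_plus = A_minus = 0.001`, `tau_pos = tau_neg = 10`,
#' `w_max = 0.5`, `w_min = -0.5`; intrinsic plasticity
#' `theta_pos = 0.001`, `theta_neg = 1e-6`; pruner `sp_thresh = 1`;
#' classifier `alpha = 1`, `mod = 0.8`, `d = 0.001`. The hidden-layer size
#' (`n_hidden = 100`) and the Gaussian init sd (`sigma_init = 0.1`) are
#' implementation choices exposed here.
#'
#' @param f AER threshold factor.
#' @param v_thresh,v_rest,R,C LIF membrane constants.
#' @param A_plus,A_minus,tau_pos,tau_neg,w_max,w_min STDP constants.
#' @param theta_pos,theta_neg Intrinsic-plasticity rates.
#' @param sp_thresh Self-pruning spike-count threshold.
#' @param alpha,mod,d Rank-order classifier constants.
#' @param n_hidden Hidden-layer size.
#' @param n_init_samples Initiation samples that evolve one neuron each.
#' @param structural_plasticity Evolve-on-error / prune / eliminate? With
#'   `FALSE` the online run is the no-structural-plasticity baseline
#'   (one neuron per sample).
#' @param ip Apply intrinsic plasticity? `FALSE` gives the STDP-only
#'   ablation.
#' @param train_fraction Training share for [run_batch()].
#' @param min_errors Elimination threshold, see [eliminate_neurons()].
#' @param sigma_init Gaussian sd of the initial input weights.
#' @param pair_window STDP pairing cutoff (steps).
#' @param thr_floor_frac Intrinsic-plasticity threshold floor fraction.
#' @param positive_class Class treated as positive for sensitivity.
#' @param update_init_neurons Drift-update the winning initiation neuron's
#'   weights toward the candidate each pass? Off by default.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `onsnn_config`.
#' @export
onsnn_config <- function(f = 0.7,
                         v_thresh = 0.05, v_rest = 0, R = 1, C = 10,
                         A_plus = 0.001, A_minus = 0.001,
                         tau_pos = 10, tau_neg = 10,
                         w_max = 0.5, w_min = -0.5,
                         theta_pos = 0.001, theta_neg = 1e-6,
                         sp_thresh = 1,
                         alpha = 1, mod = 0.8, d = 0.001,
                         n_hidden = 100, n_init_samples = 15,
                         structural_plasticity = TRUE, ip = TRUE,
                         train_fraction = 0.70, min_errors = 3,
                         sigma_init = 0.1,
                         pair_window = 5 * max(tau_pos, tau_neg),
                         thr_floor_frac = 0.1,
                         positive_class = "stress",
                         update_init_neurons = FALSE,
                         seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction <= 1, n_hidden >= 1,
            n_init_samples >= 1)
  cfg <- list(
    f = f, v_thresh = v_thresh, v_rest = v_rest, R = R, C = C,
    A_plus = A_plus, A_minus = A_minus, tau_pos = tau_pos,
    tau_neg = tau_neg, w_max = w_max, w_min = w_min,
    theta_pos = theta_pos, theta_neg = theta_neg, sp_thresh = sp_thresh,
    alpha = alpha, mod = mod, d = d, n_hidden = as.integer(n_hidden),
    n_init_samples = as.integer(n_init_samples),
    structural_plasticity = isTRUE(structural_plasticity), ip = isTRUE(ip),
    train_fraction = train_fraction, min_errors = min_errors,
    sigma_init = sigma_init, pair_window = pair_window,
    thr_floor_frac = thr_floor_frac, positive_class = positive_class,
    update_init_neurons = isTRUE(update_init_neurons),
    seed = as.integer(seed)
  )
  structure(cfg, class = "onsnn_config")
}

# derive the per-module parameter objects from an onsnn_config
config_params <- function(config) {
  list(
    lif = lif_params(v_thresh_init = config$v_thresh, v_rest = config$v_rest,
                     R = config$R, C = config$C,
                     theta_pos = config$theta_pos,
                     theta_neg = config$theta_neg,
                     thr_floor_frac = config$thr_floor_frac),
    stdp = stdp_params(A_plus = config$A_plus, A_minus = config$A_minus,
                       tau_pos = config$tau_pos, tau_neg = config$tau_neg,
                       w_max = config$w_max, w_min = config$w_min,
                       pair_window = config$pair_window),
    ro = ro_params(alpha = config$alpha, mod = config$mod, d = config$d)
  )
}

#' Initialize network state
#'
#' Builds the input weights (Gaussian, seeded), the hidden population and
#' an empty output repository.
#'
#' @param n_inputs Number of input channels.
#' @param config An [onsnn_config()].
#' @return A list of class `onsnn_state`.
#' @export
init_network <- function(n_inputs, config = onsnn_config()) {
  p <- config_params(config)
  structure(
    list(
      W = init_weights(n_inputs, config$n_hidden, seed = config$seed,
                       sigma = config$sigma_init, params = p$stdp),
      pop = lif_population(config$n_hidden, p$lif),
      repo = new_repository(),
      params = p, config = config,
      n_seen = 0L, n_scored = 0L, acc = 0,
      received = 0, generated = 0,
      cum_spike_counts = rep(0, config$n_hidden),
      class_set = character(0)
    ),
    class = "onsnn_state"
  )
}

#' Process one stream sample (test-then-train)
#'
#' The full per-sample pipeline: AER-encode; propagate through the hidden
#' layer (intrinsic plasticity each step); apply end-of-sample STDP; build
#' the rank-order candidate; TEST by nearest-neighbour classification; and
#' TRAIN only when the prediction was wrong (or during initiation), by
#' evolving a labelled output neuron, self-pruning low-firing hidden
#' neurons and eliminating persistently wrong output neurons. During the
#' first `n_init_samples` samples a neuron is evolved unconditionally and
#' predictions, though logged from the second sample onward, are not scored;
#' prequential scoring and the error-driven machinery begin at the reference
#' point just after initiation.
#'
#' @param state An `onsnn_state` from [init_network()].
#' @param segment The sample's [eeg_segment()].
#' @param label True class label.
#' @return A list with the updated `state` and a one-row `outcome` tibble.
#' @export
process_sample <- function(state, segment, label) {
  if (!inherits(state, "onsnn_state")) {
    stop("`state` must be created with init_network().", call. = FALSE)
  }
  config <- state$config
  label <- as.character(label)
  state$n_seen <- state$n_seen + 1L
  idx <- state$n_seen
  state$class_set <- union(state$class_set, label)

  events <- aer_encode(segment, f = config$f)
  # segments are non-contiguous excerpts: membrane state does not carry
  # across samples, only the slow homeostatic thresholds do
  state$pop$v <- rep(state$params$lif$v_rest, state$pop$n)
  state$pop$last_spiked <- rep(FALSE, state$pop$n)
  prop <- propagate_hidden(state$pop, events, state$W, state$params$lif,
                           ip = config$ip)
  state$pop <- prop$pop
  state$W <- stdp_apply(state$W, events, prop$raster, state$params$stdp)
  candidate <- rank_order_vector(prop$raster, state$params$ro)

  n_received <- sum(events != 0L)
  n_generated <- sum(prop$raster)
  state$received <- state$received + n_received
  state$generated <- state$generated + n_generated
  state$cum_spike_counts <- state$cum_spike_counts + prop$spike_counts

  initiation <- idx <= config$n_init_samples
  predicted <- NA_character_
  distance <- NA_real_
  correct <- NA
  if (nrow(state$repo) > 0L) {
    cls <- classify_candidate(candidate, state$repo)
    predicted <- cls$label
    distance <- cls$distance
    correct <- identical(predicted, label)
    if (!initiation) {
      # the initiation phase builds the repository; scoring (and the
      # error-driven machinery) begins at the reference point t_init just
      # after it
      state$repo <- record_win(state$repo, cls$winner_id, correct)
      state$n_scored <- state$n_scored + 1L
      state$acc <- prequential_update(state$acc, correct, state$n_scored)
    }
    if (config$update_init_neurons && state$repo$is_initiation[
          match(cls$winner_id, state$repo$id)]) {
      i <- match(cls$winner_id, state$repo$id)
      w <- state$repo$weights[[i]]
      state$repo$weights[[i]] <- w + config$d * sign(candidate - w)
    }
  }

  pruned <- 0L
  evolved <- FALSE
  eliminated <- 0L
  if (config$structural_plasticity) {
    if (initiation) {
      state$repo <- evolve_neuron(state$repo, candidate, label, idx,
                                  is_initiation = TRUE)
      evolved <- TRUE
    } else if (isFALSE(correct)) {
      state$repo <- evolve_neuron(state$repo, candidate, label, idx)
      evolved <- TRUE
    }
    if (!initiation && isFALSE(correct)) {
      # "low spiking probability" is judged on activity accumulated over the
      # stream so far, not on the single sample just seen
      before_thr <- state$pop$v_thr
      state$pop <- self_prune(state$pop, state$cum_spike_counts,
                              config$sp_thresh)
      pruned <- sum(state$pop$v_thr != before_thr)
      n_before <- nrow(state$repo)
      state$repo <- eliminate_neurons(state$repo, config$min_errors)
      eliminated <- n_before - nrow(state$repo)
    }
  } else {
    # no structural plasticity: one neuron per input sample, never pruned
    state$repo <- evolve_neuron(state$repo, candidate, label, idx,
                                is_initiation = initiation)
    evolved <- TRUE
  }

  outcome <- tibble::tibble(
    index = idx, label = label, predicted = predicted,
    scored = !initiation && !is.na(correct),
    correct = correct, distance = distance,
    repo_size = nrow(state$repo),
    received = n_received, generated = n_generated,
    evolved = evolved, pruned = pruned, eliminated = eliminated,
    acc_pre = if (state$n_scored > 0) state$acc else NA_real_
  )
  list(state = state, outcome = outcome)
}

#' Run the online test-then-train loop over a stream
#'
#' Processes each sample exactly once, in order, scoring every prediction
#' prequentially. With `structural_plasticity = TRUE` in the config this is
#' the full online neuroplasticity network; with `FALSE` it is the online
#' baseline without structural plasticity, which evolves one output neuron
#' per sample.
#'
#' @param stream A tibble with columns `label` and `segment` (list of
#'   [eeg_segment()]), e.g. from [generate_stream()] or [read_stream_dir()].
#' @param config An [onsnn_config()].
#' @return An `onsnn_result`: outcome log, prequential trace, repository,
#'   weights, population and a summary (final accuracy, sensitivity, spike
#'   ratio, output-neuron count). See [glance.onsnn_result()].
#' @export
run_online <- function(stream, config = onsnn_config()) {
  stopifnot(nrow(stream) > 0)
  state <- init_network(nrow(stream$segment[[1]]$values), config)
  rownames(state$W) <- stream$segment[[1]]$channel_names
  outcomes <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    step <- process_sample(state, stream$segment[[i]], stream$label[i])
    state <- step$state
    outcomes[[i]] <- step$outcome
  }
  outcomes <- dplyr::bind_rows(outcomes)
  finalize_result(state, outcomes, mode = "online")
}

#' Run the batch-mode baseline (train/test split, no structural plasticity)
#'
#' The first `round(train_fraction * n)` samples each evolve one labelled
#' output neuron (with STDP and intrinsic plasticity active); the remaining
#' samples are classified with all learning frozen and scored by standard
#' accuracy.
#'
#' @inheritParams run_online
#' @return An `onsnn_result` with `mode = "batch"`.
#' @export
run_batch <- function(stream, config = onsnn_config()) {
  n <- nrow(stream)
  # 0.7 * 72 must give the canonical 50/22 split, so round, not ceiling
  n_train <- round(config$train_fraction * n)
  if (n_train >= n) {
    stop("`train_fraction` leaves an empty test set.", call. = FALSE)
  }
  state <- init_network(nrow(stream$segment[[1]]$values), config)
  rownames(state$W) <- stream$segment[[1]]$channel_names
  p <- state$params
  outcomes <- vector("list", n)
  for (i in seq_len(n_train)) {
    events <- aer_encode(stream$segment[[i]], f = config$f)
    state$pop$v <- rep(p$lif$v_rest, state$pop$n)
    state$pop$last_spiked <- rep(FALSE, state$pop$n)
    prop <- propagate_hidden(state$pop, events, state$W, p$lif,
                             ip = config$ip)
    state$pop <- prop$pop
    state$W <- stdp_apply(state$W, events, prop$raster, p$stdp)
    candidate <- rank_order_vector(prop$raster, p$ro)
    state$repo <- evolve_neuron(state$repo, candidate, stream$label[i], i,
                                is_initiation = TRUE)
    state$received <- state$received + sum(events != 0L)
    state$generated <- state$generated + sum(prop$raster)
    outcomes[[i]] <- tibble::tibble(
      index = i, label = as.character(stream$label[i]),
      predicted = NA_character_, scored = FALSE, correct = NA,
      distance = NA_real_,
      repo_size = nrow(state$repo), received = sum(events != 0L),
      generated = sum(prop$raster), evolved = TRUE, pruned = 0L,
      eliminated = 0L, acc_pre = NA_real_
    )
  }
  frozen_pop <- state$pop
  frozen_pop$v <- rep(p$lif$v_rest, frozen_pop$n)
  frozen_pop$last_spiked <- rep(FALSE, frozen_pop$n)
  for (i in (n_train + 1L):n) {
    events <- aer_encode(stream$segment[[i]], f = config$f)
    prop <- propagate_hidden(frozen_pop, events, state$W, p$lif, ip = FALSE)
    candidate <- rank_order_vector(prop$raster, p$ro)
    cls <- classify_candidate(candidate, state$repo)
    correct <- identical(cls$label, as.character(stream$label[i]))
    state$n_scored <- state$n_scored + 1L
    state$acc <- prequential_update(state$acc, correct, state$n_scored)
    state$received <- state$received + sum(events != 0L)
    state$generated <- state$generated + sum(prop$raster)
    outcomes[[i]] <- tibble::tibble(
      index = i, label = as.character(stream$label[i]),
      predicted = cls$label, scored = TRUE, correct = correct,
      distance = cls$distance,
      repo_size = nrow(state$repo), received = sum(events != 0L),
      generated = sum(prop$raster), evolved = FALSE, pruned = 0L,
      eliminated = 0L, acc_pre = state$acc
    )
  }
  state$n_seen <- n
  state$class_set <- unique(as.character(stream$label))
  finalize_result(state, dplyr::bind_rows(outcomes), mode = "batch")
}

# assemble the result object from final state + outcome log
finalize_result <- function(state, outcomes, mode) {
  scored <- outcomes[outcomes$scored, ]
  trace <- tibble::tibble(index = scored$index,
                          correct = as.logical(scored$correct),
                          acc_pre = scored$acc_pre)
  classes <- sort(unique(c(state$class_set, stats::na.omit(scored$predicted))))
  conf <- confusion_matrix(scored$label, scored$predicted, classes)
  pos <- state$config$positive_class
  sens <- if (pos %in% rownames(conf) && sum(conf[pos, ]) > 0) {
    class_sensitivity(conf, pos)
  } else NA_real_
  summary <- list(
    mode = mode,
    n_samples = state$n_seen,
    n_scored = nrow(scored),
    accuracy = if (nrow(scored)) state$acc else NA_real_,
    sensitivity = sens,
    n_output_neurons = nrow(state$repo),
    spikes_received = state$received,
    spikes_generated = state$generated,
    spike_ratio = if (state$received > 0) {
      spike_ratio(state$received, state$generated)
    } else NA_real_
  )
  structure(
    list(outcomes = outcomes, trace = trace, repository = state$repo,
         weights = state$W, population = state$pop, confusion = conf,
         config = state$config, mode = mode, summary = summary),
    class = "onsnn_result"
  )
}

#' @export
print.onsnn_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<onsnn_result: %s mode>\n", s$mode))
  cat(sprintf("  samples: %d (%d scored)\n", s$n_samples, s$n_scored))
  cat(sprintf("  %s accuracy: %.4f\n",
              if (s$mode == "online") "final prequential" else "test",
              s$accuracy))
  if (!is.na(s$sensitivity)) {
    cat(sprintf("  sensitivity (%s): %.4f\n",
                x$config$positive_class, s$sensitivity))
  }
  cat(sprintf("  output neurons: %d\n", s$n_output_neurons))
  cat(sprintf("  hidden spike ratio (generated/received): %.4g\n",
              s$spike_ratio))
  invisible(x)
}

#' Repeat an online experiment over several seeds
#'
#' Re-runs [run_online()] (or [run_batch()]) with fresh weight
#' initializations, mirroring the repeated pseudo-random-initiation
#' protocol under which streaming results are reported as mean and sd.
#'
#' @param stream A stream tibble.
#' @param config Base [onsnn_config()]; its seed is replaced per repetition.
#' @param seeds Integer vector of seeds, one per repetition.
#' @param mode `"online"` or `"batch"`.
#' @return A tibble with one row per repetition (seed, accuracy,
#'   sensitivity, output-neuron count, spike ratio).
#' @export
run_repetitions <- function(stream, config = onsnn_config(),
                            seeds = 1:30, mode = c("online", "batch")) {
  mode <- match.arg(mode)
  runner <- if (mode == "online") run_online else run_batch
  purrr::map_dfr(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    r <- runner(stream, cfg)
    tibble::tibble(seed = s, accuracy = r$summary$accuracy,
                   sensitivity = r$summary$sensitivity,
                   n_output_neurons = r$summary$n_output_neurons,
                   spike_ratio = r$summary$spike_ratio)
  })
}
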