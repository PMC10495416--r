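#' Hidden-layer parameters: membrane and intrinsic plasticity
#'
#' Leaky integrate-and-fire (LIF) membrane constants and the intrinsic
#' plasticity (IP) learning rates that adapt each neuron's firing
#' threshold. Defaults are the network's standard operating point:
#' `v_thresh_init = 0.05`, `v_rest = 0`, `R = 1`, `C = 10` (so the membrane
#' time constant is `tau_m = R * C = 10` integration steps),
#' `theta_pos = 0.001` and `theta_neg = 1e-6`.
#'
#' The integration step `dt` is one sample period of the input signal,
#' treated as a unit step. `thr_floor_frac` bounds IP down-regulation:
#' thresholds never fall below `thr_floor_frac * v_thresh_init`, keeping
#' them strictly above the resting potential.
#'
#' @param v_thresh_init Initial firing threshold (volts).
#' @param v_rest Resting potential (volts).
#' @param R Membrane resistance.
#' @param C Membrane capacitance.
#' @param dt Integration step (sample periods).
#' @param theta_pos IP up-regulation rate (applied after a spike).
#' @param theta_neg IP down-regulation rate (applied after silence).
#' @param thr_floor_frac Threshold floor as a fraction of `v_thresh_init`.
#'
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(v_thresh_init = 0.05, v_rest = 0, R = 1, C = 10,
                       dt = 1, theta_pos = 0.001, theta_neg = 1e-6,
                       thr_floor_frac = 0.1) {
  stopifnot(R > 0, C > 0, dt > 0, theta_pos >= 0, theta_neg >= 0,
            v_thresh_init > v_rest, thr_floor_frac > 0)
  structure(
    list(v_thresh_init = v_thresh_init, v_rest = v_rest, R = R, C = C,
         dt = dt, tau_m = R * C, theta_pos = theta_pos,
         theta_neg = theta_neg, thr_floor_frac = thr_floor_frac),
    class = "lif_params"
  )
}

#' Create a population of LIF neurons with adaptive thresholds
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object.
#' @return A list of class `lif_population` with membrane potentials `v`,
#'   per-neuron thresholds `v_thr`, the initial threshold `v_init`, and the
#'   previous-step spike indicator `last_spiked`.
#' @export
lif_population <- function(n, params = lif_params()) {
  stopifnot(n >= 1)
  structure(
    list(v = rep(params$v_rest, n),
         v_thr = rep(params$v_thresh_init, n),
         v_init = params$v_thresh_init,
         last_spiked = rep(FALSE, n),
         n = as.integer(n)),
    class = "lif_population"
  )
}

#' @export
print.lif_population <- function(x, ...) {
  cat(sprintf("<lif_population> %d neurons; v in [%.4g, %.4g]; v_thr in [%.4g, %.4g]\n",
              x$n, min(x$v), max(x$v), min(x$v_thr), max(x$v_thr)))
  invisible(x)
}

#' One forward-Euler LIF integration step
#'
#' Updates membrane potentials by
#' `v <- v + (dt / tau_m) * (v_rest - v + R * I)`; neurons whose potential
#' reaches their threshold (`v >= v_thr`) emit a spike and reset to
#' `v_rest`. There is no refractory period.
#'
#' @param pop A [lif_population()].
#' @param I Numeric input-current vector, one entry per neuron.
#' @param params A [lif_params()].
#' @return A list with the updated `pop` and the logical `spikes` vector.
#' @export
lif_step <- function(pop, I, params = lif_params()) {
  if (length(I) != pop$n) {
    stop(sprintf("Input current has length %d but population has %d neurons.",
                 length(I), pop$n), call. = FALSE)
  }
  v <- pop$v + (params$dt / params$tau_m) * (params$v_rest - pop$v + params$R * I)
  spikes <- v >= pop$v_thr
  v[spikes] <- params$v_rest
  pop$v <- v
  pop$last_spiked <- spikes
  list(pop = pop, spikes = spikes)
}

#' Intrinsic plasticity threshold update
#'
#' Homeostatic threshold regulation applied once per time step, after the
#' membrane update: a neuron that spiked on the previous step has its
#' threshold raised by `N * theta_pos * v_init`; a silent neuron has it
#' lowered by `N * theta_neg * v_init`. Thresholds are floored at
#' `thr_floor_frac * v_init` so down-regulation cannot push them to the
#' resting potential.
#'
#' @inheritParams lif_step
#' @return The updated population.
#' @export
ip_update <- function(pop, params = lif_params()) {
  up <- pop$n * params$theta_pos * pop$v_init
  down <- pop$n * params$theta_neg * pop$v_init
  thr <- pop$v_thr + ifelse(pop$last_spiked, up, -down)
  pop$v_thr <- pmax(thr, params$thr_floor_frac * pop$v_init)
  pop
}

#' Propagate one spike train through the hidden layer
#'
#' Runs the full per-sample hidden-layer dynamics: at every time step the
#' input current to neuron j is the weighted sum of the signed input events,
#' `I_j(t) = sum_i W[i, j] * s_i(t)`; the membrane is integrated by
#' [lif_step()] and, when `ip` is `TRUE`, thresholds adapt by [ip_update()].
#'
#' @param pop A [lif_population()].
#' @param events A `spike_train` (channels x timepoints, entries -1/0/1).
#' @param W Weight matrix, channels x neurons.
#' @param params A [lif_params()].
#' @param ip Apply intrinsic plasticity each step? Default `TRUE`.
#' @return A list with the updated `pop`, the logical `raster`
#'   (neurons x timepoints) of hidden spikes, and `spike_counts` per neuron.
#' @export
propagate_hidden <- function(pop, events, W, params = lif_params(), ip = TRUE) {
  stopifnot(nrow(W) == nrow(events), ncol(W) == pop$n)
  # input current is state-independent: compute all steps in one product
  I_all <- crossprod(W, unclass(events))            # neurons x timepoints
  n_t <- ncol(I_all)
  raster <- matrix(FALSE, nrow = pop$n, ncol = n_t)
  coef <- params$dt / params$tau_m
  v <- pop$v
  v_thr <- pop$v_thr
  up <- pop$n * params$theta_pos * pop$v_init
  down <- pop$n * params$theta_neg * pop$v_init
  floor_thr <- params$thr_floor_frac * pop$v_init
  for (t in seq_len(n_t)) {
    v <- v + coef * (params$v_rest - v + params$R * I_all[, t])
    sp <- v >= v_thr
    v[sp] <- params$v_rest
    raster[, t] <- sp
    if (ip) {
      v_thr <- pmax(v_thr + ifelse(sp, up, -down), floor_thr)
    }
  }
  pop$v <- v
  pop$v_thr <- v_thr
  pop$last_spiked <- raster[, n_t]
  list(pop = pop, raster = raster, spike_counts = rowSums(raster))
}

#' Serialize / restore a population snapshot
#'
#' JSON round-trip of the hidden-layer state, for checkpoint and resume.
#'
#' @param pop A [lif_population()].
#' @param path File path to write to / read from.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns the restored `lif_population`.
#' @export
write_population <- function(pop, path) {
  jsonlite::write_json(unclass(pop), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(v = as.numeric(x$v), v_thr = as.numeric(x$v_thr),
         v_init = as.numeric(x$v_init),
         last_spiked = as.logical(x$last_spiked), n = as.integer(x$n)),
    class = "lif_population"
  )
}
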