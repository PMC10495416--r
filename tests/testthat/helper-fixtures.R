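# small, fast stream configurations used across the suite

# 12-sample, 0.5-s stream: cheap enough for per-test runs
small_synth <- function(seed = 1L, ...) {
  synth_config(n_samples = 12, class_counts = c(4, 4, 4),
               duration = 0.5, seed = seed, ...)
}

small_stream <- function(seed = 1L, ...) {
  generate_stream(small_synth(seed = seed, ...))
}

# the full-size study stream: 72 samples, 24 per class, 5 s at 256 Hz
study_stream <- function(seed = 1L) {
  generate_stream(synth_config(seed = seed))
}

# mid-stream class swap used as the standard concept-drift protocol
swap_drift <- function(stream, at = 37L) {
  inject_concept_drift(stream, at = at,
                       c(stress = "positive", positive = "stress",
                         neutral = "neutral"))
}

# brute-force STDP oracle: explicit loop over every spike pair
stdp_bruteforce <- function(W, pre_events, post_raster, params) {
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      pre_t <- which(pre_events[i, ] != 0)
      post_t <- which(post_raster[j, ] != 0)
      dw <- 0
      for (tp in pre_t) {
        for (tq in post_t) {
          dt <- tq - tp
          if (dt > 0 && dt <= params$pair_window) {
            dw <- dw + params$A_plus * exp(-dt / params$tau_pos)
          } else if (dt < 0 && dt >= -params$pair_window) {
            dw <- dw - params$A_minus * exp(dt / params$tau_neg)
          }
        }
      }
      W[i, j] <- W[i, j] + dw
    }
  }
  pmin(pmax(W, params$w_min), params$w_max)
}

# random ternary pre raster / logical post raster pair
random_rasters <- function(n_pre, n_post, n_t, p_pre = 0.2, p_post = 0.15) {
  pre <- matrix(sample(c(-1L, 0L, 1L), n_pre * n_t, replace = TRUE,
                       prob = c(p_pre / 2, 1 - p_pre, p_pre / 2)),
                nrow = n_pre)
  post <- matrix(stats::runif(n_post * n_t) < p_post, nrow = n_post)
  list(pre = pre, post = post)
}
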