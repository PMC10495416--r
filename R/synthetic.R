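#' Configuration for the synthetic EEG-like stream generator
#'
#' Generates labelled multichannel segments with class-conditional spectral
#' signatures: each class mixes the four canonical EEG bands (delta 1-4 Hz,
#' theta 4-8, alpha 8-13, beta 13-30) with its own relative amplitudes, on
#' top of 1/f ("pink") and white noise. Defaults emulate the acquisition
#' geometry the network targets: 4 channels (FP1, FP2, T7, T8) at 256 Hz,
#' 5-second segments (1280 points), 72 segments per stream, 24 per class
#' over the classes stress / neutral / positive.
#'
#' The default class profiles follow the usual stress-EEG contrast of
#' suppressed alpha with elevated beta under stress and the reverse under
#' positive affect, with a class-specific channel topography (beta elevation
#' strongest over the frontal channels and right hemisphere under stress,
#' alpha elevation strongest over the temporal channels under positive
#' affect). They are deliberately well separated so a stream is learnable by
#' construction, and channel-asymmetric so the interpretability analyses
#' (per-channel synaptic fan-out) have structure to recover.
#'
#' @param n_channels Number of channels.
#' @param channel_names Channel labels.
#' @param sampling_rate Hz.
#' @param duration Segment length in seconds.
#' @param n_samples Segments per stream.
#' @param classes Class labels.
#' @param class_counts Per-class counts; must sum to `n_samples`.
#' @param band_profiles Named list: class -> either one numeric vector of
#'   relative band amplitudes (names `delta`, `theta`, `alpha`, `beta`),
#'   applied to every channel, or a list of one such vector per channel
#'   (class-specific topography).
#' @param amplitude Overall signal scale (microvolts).
#' @param pink_sd Sd of the 1/f noise component (same units, pre-`amplitude`
#'   scale relative to the unit band amplitudes).
#' @param pink_exponent Spectral exponent of the 1/f noise.
#' @param white_sd Sd of the white-noise component.
#' @param noise_lowpass Low-pass cutoff (Hz) applied to the noise, mirroring
#'   the low-pass filtering preprocessed EEG has already undergone before it
#'   reaches the encoder; `Inf` disables it.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 4,
                         channel_names = c("FP1", "FP2", "T7", "T8"),
                         sampling_rate = 256, duration = 5,
                         n_samples = 72,
                         classes = c("stress", "neutral", "positive"),
                         class_counts = rep(n_samples / length(classes),
                                            length(classes)),
                         band_profiles = default_band_profiles(),
                         amplitude = 10, pink_sd = 0.5,
                         pink_exponent = 1, white_sd = 0.2,
                         noise_lowpass = 50,
                         seed = 1L) {
  stopifnot(length(channel_names) == n_channels,
            sum(class_counts) == n_samples,
            length(class_counts) == length(classes),
            setequal(names(band_profiles), classes))
  band_profiles <- lapply(band_profiles, function(p) {
    if (!is.list(p)) p <- rep(list(p), n_channels)
    stopifnot(length(p) == n_channels,
              all(vapply(p, function(q) length(q) == 4 && all(q >= 0),
                         logical(1))))
    p
  })
  structure(
    list(n_channels = as.integer(n_channels), channel_names = channel_names,
         sampling_rate = sampling_rate, duration = duration,
         n_samples = as.integer(n_samples), classes = classes,
         class_counts = as.integer(class_counts),
         band_profiles = band_profiles, amplitude = amplitude,
         pink_sd = pink_sd, pink_exponent = pink_exponent,
         white_sd = white_sd, noise_lowpass = noise_lowpass,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default class band profiles with channel topography
#'
#' Relative band amplitudes (delta, theta, alpha, beta) per class and
#' channel, for the default montage FP1, FP2, T7, T8: stress suppresses
#' alpha and elevates beta, most strongly frontally and on the right;
#' positive affect elevates alpha, most strongly temporally; neutral is
#' balanced with mild topography.
#'
#' @return A named list: class -> list of 4 per-channel amplitude vectors.
#' @export
default_band_profiles <- function() {
  pr <- function(d, t, a, b) c(delta = d, theta = t, alpha = a, beta = b)
  list(
    stress = list(FP1 = pr(0.30, 0.40, 0.30, 1.30),
                  FP2 = pr(0.30, 0.40, 0.25, 1.50),
                  T7  = pr(0.40, 0.50, 0.50, 0.90),
                  T8  = pr(0.35, 0.45, 0.40, 1.10)),
    neutral = list(FP1 = pr(0.50, 0.60, 0.90, 0.55),
                   FP2 = pr(0.50, 0.60, 0.95, 0.50),
                   T7  = pr(0.55, 0.65, 1.05, 0.45),
                   T8  = pr(0.50, 0.60, 1.00, 0.50)),
    positive = list(FP1 = pr(0.30, 0.50, 1.30, 0.35),
                    FP2 = pr(0.30, 0.50, 1.40, 0.30),
                    T7  = pr(0.35, 0.55, 1.70, 0.25),
                    T8  = pr(0.30, 0.50, 1.60, 0.30))
  )
}

# canonical EEG band edges in Hz
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# brick-wall low-pass via FFT; emulates the anti-alias / line-noise
# low-pass filtering the network's real inputs have already undergone
lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1))) * fs / n
  X[abs(f) > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# 1/f^exponent noise of length n via spectral shaping, unit sd
pink_noise <- function(n, exponent = 1) {
  if (exponent == 0) return(stats::rnorm(n))
  half <- floor(n / 2)
  f <- seq_len(half)
  mag <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = mag[half] * cos(phase[half]))
    if (half > 1) full[n:(half + 2)] <- Conj(spec[1:(half - 1)])
  } else {
    full[n:(half + 2)] <- Conj(spec[1:(half - 1)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Generate one class-conditional segment
#'
#' Per channel: one sinusoid per EEG band, at a frequency drawn uniformly
#' within the band and a uniform random phase, with amplitude given by the
#' class (and channel) band profile; plus 1/f and white noise, band-limited
#' the way preprocessed EEG is. Deterministic for a given
#' (class, config, seed).
#'
#' @param class A class label from `config$classes`.
#' @param config A [synth_config()].
#' @param seed Integer seed for this segment.
#' @return An [eeg_segment()].
#' @export
generate_segment <- function(class, config = synth_config(), seed = 1L) {
  if (!class %in% config$classes) {
    stop(sprintf("Unknown class '%s'.", class), call. = FALSE)
  }
  profiles <- config$band_profiles[[class]]
  bands <- eeg_bands()
  n_t <- round(config$sampling_rate * config$duration)
  tm <- seq_len(n_t) / config$sampling_rate
  vals <- local_seed(seed, {
    v <- matrix(0, nrow = config$n_channels, ncol = n_t)
    for (ch in seq_len(config$n_channels)) {
      profile <- profiles[[ch]]
      x <- numeric(n_t)
      for (b in names(bands)) {
        amp <- profile[[b]]
        if (amp > 0) {
          freq <- stats::runif(1, bands[[b]][1], bands[[b]][2])
          phase <- stats::runif(1, 0, 2 * pi)
          x <- x + amp * sin(2 * pi * freq * tm + phase)
        }
      }
      noise <- numeric(n_t)
      if (config$pink_sd > 0) {
        noise <- noise + config$pink_sd * pink_noise(n_t, config$pink_exponent)
      }
      if (config$white_sd > 0) {
        noise <- noise + stats::rnorm(n_t, sd = config$white_sd)
      }
      if (is.finite(config$noise_lowpass)) {
        noise <- lowpass(noise, config$sampling_rate, config$noise_lowpass)
      }
      v[ch, ] <- x + noise
    }
    v * config$amplitude
  })
  eeg_segment(vals, sampling_rate = config$sampling_rate,
              channel_names = config$channel_names)
}

#' Generate a labelled synthetic stream
#'
#' Draws a seeded shuffle of the class sequence with exact per-class counts
#' and materializes one segment per sample. Every sample carries both its
#' `label` and the `generator_class` that produced it; the two differ only
#' after concept drift is injected.
#'
#' @param config A [synth_config()].
#' @return A tibble of class `onsnn_stream` with columns `index`, `label`,
#'   `generator_class`, `segment` (list of [eeg_segment()]), and the config
#'   stored as an attribute.
#' @export
generate_stream <- function(config = synth_config()) {
  classes <- rep(config$classes, times = config$class_counts)
  out <- local_seed(config$seed, {
    ord <- sample(seq_along(classes))
    seeds <- sample.int(.Machine$integer.max - 1L, config$n_samples)
    cls <- classes[ord]
    segs <- purrr::map2(cls, seeds,
                        function(cl, s) generate_segment(cl, config, seed = s))
    tibble::tibble(index = seq_len(config$n_samples), label = cls,
                   generator_class = cls, segment = segs)
  })
  attr(out, "config") <- config
  class(out) <- c("onsnn_stream", class(out))
  out
}

#' Inject input drift into a stream
#'
#' From sample `at` onward the signal is rescaled by `scale` (so per-sample
#' variance scales by `scale^2`); labels are untouched. This changes the
#' input distribution without touching class posteriors.
#'
#' @param stream An `onsnn_stream`.
#' @param at 1-based sample index at which the drift starts.
#' @param scale Amplitude rescaling factor.
#' @return The drifted stream.
#' @export
inject_input_drift <- function(stream, at, scale) {
  if (at < 1 || at > nrow(stream)) {
    stop("`at` must be a valid sample index.", call. = FALSE)
  }
  idx <- which(stream$index >= at)
  stream$segment[idx] <- purrr::map(stream$segment[idx], function(seg) {
    seg$values <- seg$values * scale
    seg
  })
  stream
}

#' Inject concept drift into a stream
#'
#' From sample `at` onward the class labels are permuted by `mapping` while
#' the generating processes are unchanged: a segment produced by the
#' generator for class c is now labelled `mapping[c]`. Class posteriors
#' change; the marginal input distribution does not.
#'
#' @param stream An `onsnn_stream`.
#' @param at 1-based sample index at which the drift starts.
#' @param mapping Named character vector, a bijection over the class set
#'   (e.g. `c(stress = "positive", positive = "stress", neutral = "neutral")`).
#' @return The drifted stream.
#' @export
inject_concept_drift <- function(stream, at, mapping) {
  classes <- unique(stream$generator_class)
  if (!setequal(names(mapping), classes) ||
      !setequal(unname(mapping), classes) ||
      anyDuplicated(unname(mapping))) {
    stop("`mapping` must be a bijection over the stream's classes.",
         call. = FALSE)
  }
  if (at < 1 || at > nrow(stream)) {
    stop("`at` must be a valid sample index.", call. = FALSE)
  }
  idx <- stream$index >= at
  stream$label[idx] <- unname(mapping[stream$generator_class[idx]])
  stream
}

#' Per-band spectral power of a segment
#'
#' Periodogram power summed within each canonical EEG band, averaged over
#' channels. Used by the nearest-band-power reference classifier and by
#' tests that check the generator's class signatures are recoverable.
#'
#' @param segment An [eeg_segment()].
#' @return A named numeric vector (delta, theta, alpha, beta).
#' @export
band_powers <- function(segment) {
  v <- segment$values
  n <- ncol(v)
  fs <- segment$sampling_rate
  freqs <- (seq_len(floor(n / 2))) * fs / n
  bands <- eeg_bands()
  pw <- matrix(0, nrow = nrow(v), ncol = length(bands),
               dimnames = list(NULL, names(bands)))
  for (ch in seq_len(nrow(v))) {
    sp <- Mod(stats::fft(v[ch, ] - mean(v[ch, ])))^2 / n
    sp <- sp[2:(floor(n / 2) + 1)]
    for (b in names(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
      pw[ch, b] <- sum(sp[sel])
    }
  }
  colMeans(pw)
}

#' Nearest-band-power reference classifier
#'
#' A deliberately trivial prequential baseline: each sample is classified
#' to the class whose mean band-power profile (normalized to unit sum) is
#' nearest in Euclidean distance among the samples seen so far, then added
#' to the pool. Serves as a separability floor for generated streams, not
#' as a competing method.
#'
#' @param stream An `onsnn_stream`.
#' @return Prequential accuracy over samples 2..n.
#' @export
band_power_baseline <- function(stream) {
  feats <- t(vapply(stream$segment, function(s) {
    p <- band_powers(s)
    p / sum(p)
  }, numeric(4)))
  labels <- stream$label
  correct <- logical(nrow(stream) - 1L)
  for (i in 2:nrow(stream)) {
    seen <- seq_len(i - 1L)
    cents <- rowsum(feats[seen, , drop = FALSE], labels[seen])
    cents <- cents / as.vector(table(labels[seen])[rownames(cents)])
    d <- sqrt(rowSums((cents - matrix(feats[i, ], nrow(cents), 4,
                                      byrow = TRUE))^2))
    correct[i - 1L] <- rownames(cents)[which.min(d)] == labels[i]
  }
  mean(correct)
}
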