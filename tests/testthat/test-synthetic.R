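test_that("segment generation is deterministic and respects the geometry", {
  cfg <- small_synth()
  s1 <- generate_segment("stress", cfg, seed = 5)
  s2 <- generate_segment("stress", cfg, seed = 5)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, generate_segment("stress", cfg, 6)$values))
  expect_equal(dim(s1$values), c(4, 128))
  expect_equal(s1$channel_names, c("FP1", "FP2", "T7", "T8"))
  expect_error(generate_segment("bogus", cfg), "Unknown class")
})

test_that("a noise-free single-band profile yields a pure sinusoid", {
  cfg <- synth_config(
    n_channels = 1, channel_names = "FP1", duration = 1, n_samples = 3,
    classes = c("a", "b", "c"), class_counts = c(1, 1, 1),
    band_profiles = list(a = c(delta = 0, theta = 0, alpha = 1, beta = 0),
                         b = c(delta = 1, theta = 0, alpha = 0, beta = 0),
                         c = c(delta = 0, theta = 1, alpha = 0, beta = 0)),
    pink_sd = 0, white_sd = 0)
  x <- generate_segment("a", cfg, seed = 2)$values[1, ]
  # amplitude matches and spectral mass sits on a single alpha-band line
  expect_equal(max(abs(x)), cfg$amplitude, tolerance = 0.01)
  sp <- Mod(stats::fft(x))^2
  peak <- which.max(sp[2:128])   # frequency bins 1..127 Hz
  expect_gte(peak, 8)
  expect_lte(peak, 13)
  # off-bin frequencies leak into neighbours; peak +/- 1 carries the mass
  expect_gt(sum(sp[peak + 0:2]) / sum(sp[2:128]), 0.99)
})

test_that("streams carry exact per-class counts in seeded shuffled order", {
  stream <- small_stream(seed = 3)
  expect_equal(nrow(stream), 12)
  expect_equal(as.vector(table(stream$label)), c(4, 4, 4))
  expect_identical(stream$label, stream$generator_class)
  expect_identical(small_stream(seed = 3)$label, stream$label)
  expect_false(identical(small_stream(seed = 4)$label, stream$label))
  # segments are reproducible too
  expect_identical(small_stream(seed = 3)$segment[[5]]$values,
                   stream$segment[[5]]$values)
})

test_that("class band-power rankings are recoverable from generated data", {
  cfg <- small_synth(seed = 9)
  p_stress <- band_powers(generate_segment("stress", cfg, seed = 1))
  p_pos <- band_powers(generate_segment("positive", cfg, seed = 1))
  # stress: beta dominates alpha; positive affect: the reverse
  expect_gt(p_stress[["beta"]], p_stress[["alpha"]])
  expect_gt(p_pos[["alpha"]], p_pos[["beta"]])
})

test_that("input drift rescales signal power without touching labels", {
  stream <- small_stream(seed = 6)
  drifted <- inject_input_drift(stream, at = 7, scale = 2)
  expect_identical(drifted$label, stream$label)
  v_pre <- var(as.vector(drifted$segment[[3]]$values))
  expect_equal(v_pre, var(as.vector(stream$segment[[3]]$values)))
  for (i in 7:12) {
    expect_equal(var(as.vector(drifted$segment[[i]]$values)),
                 4 * var(as.vector(stream$segment[[i]]$values)))
  }
  expect_identical(inject_input_drift(stream, 5, 1)$segment[[8]]$values,
                   stream$segment[[8]]$values)
  expect_error(inject_input_drift(stream, 99, 2), "valid sample index")
})

test_that("concept drift permutes labels while generators are untouched", {
  stream <- small_stream(seed = 6)
  map <- c(stress = "positive", positive = "stress", neutral = "neutral")
  drifted <- inject_concept_drift(stream, at = 7, mapping = map)
  expect_identical(drifted$generator_class, stream$generator_class)
  expect_identical(drifted$segment, stream$segment)
  expect_identical(drifted$label[1:6], stream$label[1:6])
  expect_identical(drifted$label[7:12],
                   unname(map[stream$generator_class[7:12]]))
  # identity mapping changes nothing
  idm <- c(stress = "stress", neutral = "neutral", positive = "positive")
  expect_identical(inject_concept_drift(stream, 7, idm)$label, stream$label)
  expect_error(inject_concept_drift(stream, 7, c(stress = "stress",
                                                 neutral = "stress",
                                                 positive = "positive")),
               "bijection")
})

test_that("a trivial band-power classifier clears the separability floor", {
  stream <- generate_stream(synth_config(seed = 42))
  expect_gt(band_power_baseline(stream), 0.9)
})
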