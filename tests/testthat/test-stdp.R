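test_that("weight initialization is seeded, bounded and Gaussian-degenerate at sigma 0", {
  W1 <- init_weights(4, 50, seed = 42)
  W2 <- init_weights(4, 50, seed = 42)
  expect_identical(W1, W2)
  expect_false(identical(W1, init_weights(4, 50, seed = 43)))
  expect_true(all(W1 >= -0.5 & W1 <= 0.5))
  expect_true(all(init_weights(3, 10, seed = 1, sigma = 0) == 0))
  # seeding is local: the global RNG stream is not disturbed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(init_weights(2, 2, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the pair kernel follows the exponential LTP/LTD windows", {
  expect_equal(stdp_pair_delta(10), 0.001 * exp(-1))
  expect_equal(stdp_pair_delta(-10), -0.001 * exp(-1))
  expect_equal(stdp_pair_delta(0), 0)
  p <- stdp_params(pair_window = 30)
  expect_equal(stdp_pair_delta(31, p), 0)
  expect_equal(stdp_pair_delta(-31, p), 0)
  expect_equal(stdp_pair_delta(30, p), 0.001 * exp(-3))
  # vectorized evaluation
  expect_equal(stdp_pair_delta(c(10, -10, 0)),
               c(0.001 * exp(-1), -0.001 * exp(-1), 0))
})

test_that("a single pre/post pair potentiates exactly one synapse", {
  W <- matrix(0, 2, 3)
  pre <- matrix(0L, 2, 20); pre[1, 5] <- 1L
  post <- matrix(FALSE, 3, 20); post[2, 15] <- TRUE
  out <- stdp_apply(W, pre, post, stdp_params())
  expect_equal(out[1, 2], 0.001 * exp(-1))
  out[1, 2] <- 0
  expect_true(all(out == 0))
})

test_that("no post spikes leaves weights unchanged; clipping holds at the rails", {
  W <- matrix(runif(6, -0.4, 0.4), 2, 3)
  pre <- matrix(sample(c(-1L, 0L, 1L), 40, replace = TRUE), 2, 20)
  expect_equal(stdp_apply(W, pre, matrix(FALSE, 3, 20), stdp_params()), W)
  # saturated weight stays exactly at w_max under net-positive updates
  Wmax <- matrix(0.5, 1, 1)
  pre1 <- matrix(0L, 1, 20); pre1[1, 5] <- 1L
  post1 <- matrix(FALSE, 1, 20); post1[1, 10] <- TRUE
  expect_equal(stdp_apply(Wmax, pre1, post1, stdp_params())[1, 1], 0.5)
})

test_that("window mismatch is rejected", {
  expect_error(stdp_apply(matrix(0, 1, 1), matrix(0L, 1, 10),
                          matrix(FALSE, 1, 12), stdp_params()),
               "same time window")
})

test_that("cumulative STDP equals the brute-force pair enumeration", {
  p <- stdp_params(pair_window = 15)
  set.seed(99)
  for (k in 1:25) {
    r <- random_rasters(n_pre = sample(2:5, 1), n_post = sample(2:5, 1),
                        n_t = sample(20:50, 1))
    W <- matrix(runif(nrow(r$pre) * nrow(r$post), -0.3, 0.3),
                nrow(r$pre), nrow(r$post))
    expect_equal(stdp_apply(W, r$pre, r$post, p),
                 stdp_bruteforce(W, r$pre, r$post, p), tolerance = 1e-12)
  }
})

test_that("every operation preserves weight bounds", {
  p <- stdp_params()
  set.seed(4)
  W <- init_weights(3, 10, seed = 8, sigma = 0.4, params = p)
  for (k in 1:10) {
    r <- random_rasters(3, 10, 60, p_pre = 0.5, p_post = 0.4)
    W <- stdp_apply(W, r$pre, r$post, p)
    expect_true(all(W >= p$w_min & W <= p$w_max))
  }
})

test_that("self-pruning raises only low-firing thresholds, to the population max", {
  p <- lif_params()
  pop <- lif_population(3, p)
  pop$v_thr <- c(0.05, 0.05, 0.08)
  out <- self_prune(pop, spike_counts = c(0, 5, 3), sp_thresh = 1)
  expect_equal(out$v_thr, c(0.08, 0.05, 0.08))
  # all neurons active: untouched
  expect_equal(self_prune(pop, c(2, 5, 3), 1)$v_thr, pop$v_thr)
  # all below threshold: everyone at the prior max
  expect_equal(self_prune(pop, c(0, 0, 0), 1)$v_thr, rep(0.08, 3))
  # never exceeds the pre-call maximum
  set.seed(11)
  pop$v_thr <- runif(3, 0.02, 0.2)
  pruned <- self_prune(pop, c(0, 0, 0), 1)
  expect_true(all(pruned$v_thr <= max(pop$v_thr)))
})

test_that("pruned neurons recover through threshold down-regulation", {
  # down-regulation rate is N * theta_neg * v_init per silent step; use a
  # rate that decays within a short horizon so the mechanism is observable
  p <- lif_params(theta_neg = 1e-4)
  pop <- lif_population(2, p)
  pop$v_thr <- c(0.05, 0.2)
  pop <- self_prune(pop, c(0, 5), 1)   # neuron 1 silenced at 0.2
  expect_equal(pop$v_thr[1], 0.2)
  for (i in 1:20000) pop <- ip_update(pop, p)  # silent throughout
  # threshold decays back below the original value: neuron can fire again
  expect_lt(pop$v_thr[1], 0.05)
  expect_gte(pop$v_thr[1], p$thr_floor_frac * p$v_thresh_init)
})

test_that("STDP+IP generates fewer hidden spikes than STDP alone", {
  stream <- small_stream(seed = 21)
  with_ip <- run_online(stream, onsnn_config(seed = 3))
  no_ip <- run_online(stream, onsnn_config(seed = 3, ip = FALSE))
  expect_lt(with_ip$summary$spikes_generated, no_ip$summary$spikes_generated)
})
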