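test_that("initiation evolves one neuron per sample regardless of correctness", {
  stream <- small_stream(seed = 2)
  cfg <- onsnn_config(seed = 1, n_init_samples = 5)
  state <- init_network(4, cfg)
  for (i in 1:5) {
    step <- process_sample(state, stream$segment[[i]], stream$label[i])
    state <- step$state
    expect_true(step$outcome$evolved)
    expect_false(step$outcome$scored)
  }
  expect_equal(nrow(state$repo), 5)
  expect_true(all(state$repo$is_initiation))
})

test_that("after initiation, training happens only on errors", {
  stream <- small_stream(seed = 2)
  res <- run_online(stream, onsnn_config(seed = 1, n_init_samples = 5))
  post <- res$outcomes[res$outcomes$index > 5, ]
  expect_true(all(post$evolved == !post$correct))
  expect_true(all(post$pruned[post$correct] == 0))
  expect_true(all(post$eliminated[post$correct] == 0))
  # correct predictions leave the repository size unchanged
  sizes <- res$outcomes$repo_size
  grow <- diff(c(5, post$repo_size))
  expect_true(all(grow[post$correct] <= 0))
})

test_that("repository growth is bounded by initiation plus errors", {
  stream <- small_stream(seed = 11)
  cfg <- onsnn_config(seed = 2, n_init_samples = 5)
  res <- run_online(stream, cfg)
  n_err <- sum(!res$outcomes$correct[res$outcomes$scored])
  expect_lte(res$summary$n_output_neurons, 5 + n_err)
})

test_that("without structural plasticity every sample evolves a neuron", {
  stream <- small_stream(seed = 11)
  res <- run_online(stream, onsnn_config(seed = 2,
                                         structural_plasticity = FALSE))
  expect_equal(res$summary$n_output_neurons, nrow(stream))
  expect_true(all(res$outcomes$evolved))
  expect_true(all(res$outcomes$pruned == 0))
})

test_that("online runs are bit-identical under a fixed seed", {
  stream <- small_stream(seed = 7)
  cfg <- onsnn_config(seed = 5, n_init_samples = 4)
  r1 <- run_online(stream, cfg)
  r2 <- run_online(stream, cfg)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$repository$weights, r2$repository$weights)
  # a different weight seed changes the run
  r3 <- run_online(stream, onsnn_config(seed = 6, n_init_samples = 4))
  expect_false(identical(r1$outcomes$predicted, r3$outcomes$predicted))
})

test_that("batch mode splits first-70% train / 30% test with a frozen model", {
  stream <- small_stream(seed = 9)          # 12 samples -> 8 train, 4 test
  cfg <- onsnn_config(seed = 1)
  res <- run_batch(stream, cfg)
  expect_equal(sum(res$outcomes$evolved), 8)
  expect_equal(sum(res$outcomes$scored), 4)
  expect_equal(res$summary$n_output_neurons, 8)
  # frozen model: a second pass over the test samples predicts identically
  res2 <- run_batch(stream, cfg)
  expect_identical(res$outcomes$predicted, res2$outcomes$predicted)
  expect_error(run_batch(stream, onsnn_config(train_fraction = 1)),
               "empty test set")
})

test_that("prequential trace in results matches the recursion on its log", {
  stream <- small_stream(seed = 13)
  res <- run_online(stream, onsnn_config(seed = 4, n_init_samples = 4))
  expect_equal(res$trace$acc_pre, prequential_trace(res$trace$correct))
  expect_equal(res$summary$accuracy,
               mean(res$trace$correct))
})

test_that("glance and tidy expose the run; autoplot builds", {
  stream <- small_stream(seed = 13)
  res <- run_online(stream, onsnn_config(seed = 4, n_init_samples = 4))
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_output_neurons, nrow(res$repository))
  expect_identical(tidy(res), res$outcomes)
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "onsnn_result")
})

test_that("repeated runs report per-seed summaries", {
  stream <- small_stream(seed = 20)
  reps <- run_repetitions(stream, onsnn_config(n_init_samples = 4),
                          seeds = 1:3)
  expect_equal(nrow(reps), 3)
  expect_true(all(reps$accuracy >= 0 & reps$accuracy <= 1))
  expect_true(all(reps$n_output_neurons >= 4))
})

test_that("structural-plasticity ablation diverges only through SP actions", {
  stream <- small_stream(seed = 30)
  cfg_on <- onsnn_config(seed = 3, n_init_samples = 4)
  cfg_off <- onsnn_config(seed = 3, n_init_samples = 4,
                          structural_plasticity = FALSE)
  on <- run_online(stream, cfg_on)
  off <- run_online(stream, cfg_off)
  # identical encoder/weights: received spike counts agree everywhere
  expect_identical(on$outcomes$received, off$outcomes$received)
  # hidden dynamics agree at least until the first SP action
  first_sp <- min(c(which(on$outcomes$pruned > 0), Inf))
  if (is.finite(first_sp) && first_sp > 1) {
    expect_identical(on$outcomes$generated[seq_len(first_sp - 1)],
                     off$outcomes$generated[seq_len(first_sp - 1)])
  }
})
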