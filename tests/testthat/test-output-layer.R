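test_that("rank-order weights follow alpha * mod^rank of first-spike order", {
  r <- matrix(FALSE, 3, 10)
  r[3, 2] <- TRUE; r[1, 4] <- TRUE; r[2, 6] <- TRUE   # order: n3, n1, n2
  w <- rank_order_vector(r, ro_params(d = 0))
  expect_equal(w, c(0.8, 0.64, 1.0))
  # a lone first spike gets the full alpha regardless of mod
  r1 <- matrix(FALSE, 1, 5); r1[1, 3] <- TRUE
  expect_equal(rank_order_vector(r1, ro_params(alpha = 2, mod = 0.3, d = 0)), 2)
})

test_that("the drift term adds d per spike step and subtracts d per silent step", {
  # first spike at t=1, then spikes at 2,3,4 and silence at 5,6
  r <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), nrow = 1)
  w <- rank_order_vector(r, ro_params(alpha = 1, mod = 0.8, d = 0.001))
  expect_equal(w, 1 + 3 * 0.001 - 2 * 0.001)   # 1.001
})

test_that("rank-order weights are strictly decreasing in rank (d = 0, mod < 1)", {
  set.seed(31)
  for (k in 1:10) {
    r <- matrix(runif(8 * 30) < 0.2, 8, 30)
    w <- rank_order_vector(r, ro_params(d = 0))
    first <- apply(r, 1, function(x) if (any(x)) which(x)[1] else NA)
    spiked <- order(first[!is.na(first)])
    ws <- sort(w[w > 0], decreasing = TRUE)
    expect_equal(length(unique(ws)), length(ws))
    if (length(ws) > 1) expect_true(all(diff(ws) < 0))
  }
})

test_that("an empty raster yields a flagged all-zero vector", {
  w <- rank_order_vector(matrix(FALSE, 4, 10))
  expect_equal(as.numeric(w), rep(0, 4))
  expect_true(attr(w, "empty"))
})

test_that("classification is nearest-neighbour with age tie-break", {
  repo <- new_repository()
  repo <- evolve_neuron(repo, c(1, 0), "A", 1, is_initiation = TRUE)
  repo <- evolve_neuron(repo, c(0, 1), "B", 2, is_initiation = TRUE)
  out <- classify_candidate(c(0.9, 0.1), repo)
  expect_equal(out$label, "A")
  expect_equal(out$distance, sqrt(0.01 + 0.01))
  # identity
  expect_equal(classify_candidate(c(0, 1), repo)$distance, 0)
  # exact tie: the older neuron wins
  tie <- classify_candidate(c(0.5, 0.5), repo)
  expect_equal(tie$winner_id, 1L)
  expect_error(classify_candidate(c(1, 1), new_repository()),
               "not initialized")
})

test_that("classification ignores repository ordering except at ties", {
  set.seed(8)
  repo <- new_repository()
  for (i in 1:6) {
    repo <- evolve_neuron(repo, runif(4), sample(c("A", "B"), 1), i)
  }
  cand <- runif(4)
  shuffled <- repo[sample(6), ]
  class(shuffled) <- class(repo)
  expect_equal(classify_candidate(cand, shuffled)$winner_id,
               classify_candidate(cand, repo)$winner_id)
})

test_that("neuron evolution appends labelled neurons with bookkeeping", {
  repo <- new_repository()
  for (i in 1:15) {
    repo <- evolve_neuron(repo, rnorm(5), c("a", "b", "c")[1 + i %% 3], i,
                          is_initiation = TRUE)
  }
  expect_equal(nrow(repo), 15)
  expect_true(all(repo$is_initiation))
  expect_equal(repo$created_at, 1:15)
  expect_true(all(repo$wins_correct == 0L & repo$wins_wrong == 0L))
})

test_that("elimination removes persistent losers but protects initiation and classes", {
  repo <- new_repository()
  repo <- evolve_neuron(repo, c(1, 0), "A", 1, is_initiation = TRUE)
  repo <- evolve_neuron(repo, c(0, 1), "B", 2)
  repo <- evolve_neuron(repo, c(1, 1), "B", 3)
  repo$wins_wrong <- c(5L, 3L, 0L)
  repo$wins_correct <- c(0L, 0L, 4L)
  out <- eliminate_neurons(repo, min_errors = 3)
  # neuron 2 (evolved, 3 wrong > 0 correct) goes; initiation neuron 1 stays
  expect_equal(out$id, c(1L, 3L))
  # sole survivor of a class is retained regardless of counters
  solo <- new_repository()
  solo <- evolve_neuron(solo, c(1, 0), "A", 1)
  solo$wins_wrong <- 9L
  expect_equal(nrow(eliminate_neurons(solo, min_errors = 3)), 1)
  # below min_errors: kept even if losing on balance
  repo$wins_wrong <- c(0L, 2L, 0L)
  repo$wins_correct <- c(0L, 1L, 0L)
  expect_equal(nrow(eliminate_neurons(repo, min_errors = 3)), 3)
})

test_that("win recording updates the right counters", {
  repo <- new_repository()
  repo <- evolve_neuron(repo, c(1, 0), "A", 1)
  repo <- record_win(repo, 1L, TRUE)
  repo <- record_win(repo, 1L, FALSE)
  repo <- record_win(repo, 1L, FALSE)
  expect_equal(repo$wins_correct, 1L)
  expect_equal(repo$wins_wrong, 2L)
  expect_error(record_win(repo, 99L, TRUE), "Unknown")
})

test_that("the repository round-trips through JSON and tidies wide", {
  repo <- new_repository()
  repo <- evolve_neuron(repo, c(0.1, -0.2, 0.3), "stress", 1,
                        is_initiation = TRUE)
  repo <- evolve_neuron(repo, c(0.5, 0.0, -0.1), "neutral", 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_repository_json(repo, path)
  back <- read_repository_json(path)
  expect_equal(back$weights, repo$weights)
  expect_equal(back$label, repo$label)
  expect_equal(back$is_initiation, repo$is_initiation)
  wide <- tidy(repo)
  expect_equal(nrow(wide), 2)
  expect_equal(wide$w2, c(-0.2, 0.0))
})
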