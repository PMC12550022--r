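test_that("the objective matches closed forms on constructed instances", {
  trip <- data.frame(worker_id = "w", set_index = 1, trial_index = 1,
                     stim_left = "a", stim_center = "b", stim_right = "c",
                     choice_position = 3L, rt_ms = 1500)
  zero <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(spose_loss(zero, trip, lambda = 0), -log(1 / 3),
               tolerance = 1e-12)

  # weights (1,1,0), observed odd = c: -log p = log(e + 2) - 1
  w <- matrix(c(1, 1, 0), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(spose_loss(w, trip, lambda = 0), log(exp(1) + 2) - 1,
               tolerance = 1e-12)

  # penalty scaling: lambda * sum(W) / n_items on top of the cross-entropy;
  # a weight sum of 10 over 2 items at lambda 0.008 contributes 0.04
  w2 <- matrix(c(4, 6), nrow = 2, dimnames = list(c("x", "y"), NULL))
  expect_equal(0.008 * sum(w2) / nrow(w2), 0.04)
  w3 <- matrix(c(4, 6, 0), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(spose_loss(w3, trip, lambda = 0.008) -
                 spose_loss(w3, trip, lambda = 0),
               0.008 * 10 / 3, tolerance = 1e-12)

  # R and C++ objective agree on random instances
  sm <- small_training_set(n_items = 10, coverage = 3, seed = 71)
  W <- generate_ground_truth(10, 4, 0.4, seed = 72)
  rownames(W) <- sort(unique(c(sm$choices$stim_left, sm$choices$stim_center,
                               sm$choices$stim_right)))
  tr <- sposer:::choices_to_trials(sm$choices, rownames(W))
  expect_equal(spose_loss(W, sm$choices, lambda = 0.02),
               sposer:::.spose_loss_cpp(W, tr$trips - 1L, tr$odd - 1L, 0.02),
               tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  for (s in 1:3) {
    truth <- generate_ground_truth(5, 3, sparsity = 0.2, seed = s)
    des <- suppressWarnings(build_design(rownames(truth), pair_coverage = 2,
                                         set_size = 10, seed = s + 10))
    ch <- simulate_dataset(truth, des, worker_profile("w"), seed = s)$choices
    W <- withr::with_seed(s, matrix(runif(15, 0.1, 1), 5, 3,
                                    dimnames = list(rownames(truth), NULL)))
    g <- spose_gradient(W, ch, lambda = 0.01)
    h <- 1e-6
    fd <- W * 0
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      Wp <- W; Wp[i, j] <- W[i, j] + h
      Wm <- W; Wm[i, j] <- W[i, j] - h
      fd[i, j] <- (spose_loss(Wp, ch, 0.01) - spose_loss(Wm, ch, 0.01)) / (2 * h)
    }
    expect_lt(max(abs(g - fd) / (abs(fd) + 1e-8)), 1e-6)
  }
})

test_that("at the zero matrix only the penalty gradient remains", {
  trip <- data.frame(worker_id = "w", set_index = 1, trial_index = 1:2,
                     stim_left = c("a", "b"), stim_center = c("b", "c"),
                     stim_right = c("c", "d"), choice_position = c(1L, 2L),
                     rt_ms = 1500)
  zero <- matrix(0, 4, 3, dimnames = list(letters[1:4], NULL))
  g <- spose_gradient(zero, trip, lambda = 0.12)
  expect_equal(unname(g), matrix(0.12 / 4, 4, 3), tolerance = 1e-12)
})

test_that("pruning drops weak dimensions strictly below threshold and sorts the rest", {
  w <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  w[1, ] <- c(0.05, 5.2, 0.3)
  out <- prune_and_sort(w, 0.1)
  expect_identical(ncol(out), 2L)
  expect_equal(unname(colSums(out)), c(5.2, 0.3))
  expect_identical(colnames(out), c("dim_001", "dim_002"))

  # a column summing exactly to the threshold survives
  w2 <- matrix(c(0.04, 0.06, 1, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_identical(ncol(prune_and_sort(w2, 0.1)), 2L)
  w3 <- w2; w3[1, 1] <- 0.039999
  expect_identical(ncol(prune_and_sort(w3, 0.1)), 1L)

  # nothing below threshold: only reordering happens
  w4 <- matrix(c(1, 1, 3, 3, 2, 2), 2, 3, dimnames = list(c("a", "b"), NULL))
  out4 <- prune_and_sort(w4, 0.1)
  expect_equal(unname(colSums(out4)), c(6, 4, 2))

  expect_warning(empty <- prune_and_sort(w * 0, 0.1), "all dimensions pruned")
  expect_identical(ncol(empty), 0L)
})

test_that("training is deterministic, respects k_init, stays non-negative and learns signal", {
  sm <- small_training_set(seed = 310)
  cfg <- fast_config(lambda = 0.01, seed = 5)
  fit1 <- spose_train(sm$choices, cfg)
  fit2 <- spose_train(sm$choices, cfg)
  expect_identical(fit1$embedding, fit2$embedding)
  expect_identical(fit1$validation_loss_history, fit2$validation_loss_history)

  expect_lte(fit1$k_effective, cfg$k_init)
  expect_true(all(fit1$embedding >= 0))
  expect_lte(length(fit1$train_loss_history), cfg$max_epochs)

  # validation loss at the stopping epoch does not exceed epoch 1
  hist <- fit1$validation_loss_history
  expect_lte(hist[fit1$stopped_epoch], hist[1])

  # well-separated 1-dimensional structure beats chance on held-out trials
  truth1 <- matrix(c(rep(2, 10), rep(0.05, 10)), ncol = 1,
                   dimnames = list(sprintf("m%02d", 1:20), NULL))
  des <- suppressWarnings(build_design(rownames(truth1), pair_coverage = 10,
                                       set_size = 32, seed = 8))
  ch <- simulate_dataset(truth1, des,
                         lapply(1:6, function(i) worker_profile(paste0("w", i))),
                         seed = 9)$choices
  fit3 <- spose_train(ch, fast_config(lambda = 0.01, seed = 6))
  expect_gte(fit3$holdout_accuracy, 1 / 3 + 0.05)

  # a different seed gives a different (but valid) fit
  fit4 <- spose_train(sm$choices, fast_config(lambda = 0.01, seed = 99))
  expect_false(identical(fit1$embedding, fit4$embedding))

  expect_error(spose_train(sm$choices[1:50, ],
                           spose_config(batch_size = 128)), "full batch")
})

test_that("the learned choice probabilities approach empirical frequencies on a saturated design", {
  # 4 items, all 4 triplets, many repeats from a generating embedding
  truth <- generate_ground_truth(4, 2, sparsity = 0.2, scale = 1.2, seed = 55)
  trips <- t(combn(rownames(truth), 3))
  reps <- 500
  trials <- data.frame(
    block = "main", set_index = 1,
    trial_index = seq_len(nrow(trips) * reps),
    stim_left = rep(trips[, 1], each = reps),
    stim_center = rep(trips[, 2], each = reps),
    stim_right = rep(trips[, 3], each = reps)
  )
  ch <- simulate_dataset(truth, structure(list(trials = trials),
                                          class = "trial_design"),
                         worker_profile("w"), seed = 56)$choices
  fit <- spose_train(ch, spose_config(profile = "reduced", k_init = 4,
                                      lambda = 0.001, max_epochs = 150,
                                      window = 30, seed = 57))
  kl <- numeric(nrow(trips))
  for (t in seq_len(nrow(trips))) {
    rows <- ch$stim_left == trips[t, 1] & ch$stim_center == trips[t, 2] &
      ch$stim_right == trips[t, 3]
    emp <- tabulate(ch$choice_position[rows], 3) / sum(rows)
    mod <- choice_probabilities(fit$embedding, trips[t, ])
    kl[t] <- sum(ifelse(emp > 0, emp * log(emp / mod), 0))
  }
  expect_lt(mean(kl), 0.05)
})
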