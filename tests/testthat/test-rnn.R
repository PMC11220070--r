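test_that("rollout mechanics respect the clock, tanh range and tie-break", {
  m <- rnn_init(hidden = 12, seed = 3)
  run <- rnn_run(m)
  expect_identical(dim(run$hidden), c(2048L, 12L, 75L))
  expect_true(all(abs(run$hidden) < 1))
  expect_identical(dim(run$decision), c(2048L, 5L))
  expect_identical(run$decision_steps, c(10L, 25L, 40L, 55L, 70L))
  # zero output weights: every output ties, deterministic no-go
  m0 <- m
  m0$D[] <- 0
  run0 <- rnn_run(m0)
  expect_true(all(run0$decision == 0L))
})

test_that("a hand-built visual follower is perfect in its context only", {
  m <- rnn_init(hidden = 2, seed = 1)
  m$U[] <- 0; m$V[] <- 0; m$F[] <- 0; m$D[] <- 0
  m$U[1, "visual_go"] <- 5; m$U[1, "visual_nogo"] <- -5
  m$D["go", 1] <- 5; m$D["nogo", 1] <- -5
  run <- rnn_run(m)
  ctx <- run$codes$context
  vis_final <- run$codes$stim[, 5] %/% 2L
  aud_final <- run$codes$stim[, 5] %% 2L
  expect_equal(mean(run$correct[ctx == 0L, 5L]), 1)
  inc_aud <- ctx == 1L & vis_final != aud_final
  expect_equal(mean(run$correct[inc_aud, 5L]), 0)   # follows the distractor
  expect_equal(mean(run$correct[ctx == 1L, 5L]), 0.5)
})

test_that("trainer loss agrees with the independent prefix-tree gradient path", {
  m <- rnn_init(hidden = 10, seed = 7)
  lg <- rnn_loss_grad_cpp(m$U, m$V, m$F, m$D)
  # single full-batch epoch: all rollouts precede the only update, so the
  # recorded epoch-1 loss is the full-dataset loss at the initial weights
  fit <- rnn_train_cpp(m$U, m$V, m$F, m$D, 1L, 1e-9, 1L, 2048L, 1L,
                       FALSE, FALSE)
  expect_equal(fit$curve$loss[1L], lg$loss, tolerance = 1e-12)
  # tree gradient matches central finite differences at spot coordinates
  eps <- 1e-6
  for (nm in c("U", "F", "D")) {
    g <- lg[[paste0("g", nm)]]
    idx <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, ]
    wp <- m; wm <- m
    wp[[nm]][idx[1], idx[2]] <- wp[[nm]][idx[1], idx[2]] + eps
    wm[[nm]][idx[1], idx[2]] <- wm[[nm]][idx[1], idx[2]] - eps
    fd <- (rnn_loss_grad_cpp(wp$U, wp$V, wp$F, wp$D)$loss -
             rnn_loss_grad_cpp(wm$U, wm$V, wm$F, wm$D)$loss) / (2 * eps)
    expect_equal(g[idx[1], idx[2]], fd, tolerance = 1e-5)
  }
})

test_that("training is deterministic in the seed and records curves", {
  m1 <- rnn_train(hidden = 8, epochs = 30, seed = 5, record_every = 10)
  m2 <- rnn_train(hidden = 8, epochs = 30, seed = 5, record_every = 10)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$F, m2$F)
  expect_identical(m1$curve, m2$curve)
  m3 <- rnn_train(hidden = 8, epochs = 30, seed = 6, record_every = 10)
  expect_false(identical(m1$U, m3$U))
  expect_true(all(c("epoch", "loss", "acc_all", "acc_congruent",
                    "acc_incongruent") %in% names(m1$curve)))
  expect_identical(first_crossing_epoch(m1, level = 0), 1)
})

test_that("weight analysis reproduces closed-form matrix power structure", {
  m <- rnn_init(hidden = 2, seed = 1)
  m$F <- matrix(c(1, -1, -1, 1), 2, 2)
  m$U[] <- 0
  m$U[1, "visual_go"] <- 1; m$U[2, "auditory_go"] <- 1
  m$U[1, "visual_nogo"] <- 1; m$U[2, "auditory_nogo"] <- 1
  aw <- analyze_weights(m, powers = 2:6)
  # F^k = 2^(k-1) F: rescaled sign pattern identical at every power
  for (nm in names(aw$ordered)) {
    expect_equal(aw$ordered[[nm]], matrix(c(1, -1, -1, 1), 2, 2))
  }
  expect_true(all(aw$block_stats$diag_mean == 1))
  expect_true(all(aw$block_stats$offdiag_mean == -1))
  # identity recurrence: powers stay identity, off-diagonal mean zero
  m$F <- diag(2)
  aw_id <- analyze_weights(m, powers = 2:3)   # includes F itself
  expect_equal(aw_id$block_stats$diag_mean, c(1, 1, 1))
  expect_equal(aw_id$block_stats$offdiag_mean, c(0, 0, 0))
})

test_that("modality index ranks follow the input weights", {
  m <- rnn_init(hidden = 4, seed = 2)
  m$U[] <- 0
  m$U[, "visual_go"] <- c(2, 1, -1, -2)
  m$U[, "auditory_go"] <- c(-2, -1, 1, 2)
  m$U[, "visual_nogo"] <- c(2, 1, -1, -2)
  m$U[, "auditory_nogo"] <- c(-2, -1, 1, 2)
  mi <- rnn_modality_index(m)
  expect_equal(mi$go$index, c(4, 2, -2, -4))
  expect_identical(mi$go$order, 1:4)
  expect_identical(mi$nogo$order, 1:4)
})

test_that("zero recurrence cannot carry the choice into later trials", {
  m <- rnn_init(hidden = 10, seed = 9)
  m$F[] <- 0
  run <- rnn_run(m)
  ds <- rnn_decision_persistence(m, run = run, ref_trial = 3, folds = 5)
  if (ds$available) {
    clock <- task_clock()
    # steps of the following trial after the reward signal switches off
    later <- ds$time_s > 3 * clock$steps_per_trial + 3
    expect_lt(mean(ds$accuracy[later]), 0.62)
  } else {
    # degenerate untrained decisions (single class): nothing to decode
    expect_true(min(ds$n_per_class) < 10)
  }
})
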