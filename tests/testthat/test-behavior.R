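test_that("choice-model likelihoods match closed forms", {
  trials <- data.frame(visual = c(1L, 0L, 1L, 0L),
                       auditory = c(0L, 1L, 1L, 0L),
                       context = "visual",
                       lick = c(1L, 0L, 1L, 0L))
  # perfect performance under the correct-modality model: clipped at 0.999
  ll <- choice_model_loglik(choice_model("correct_modality"), trials)
  expect_equal(ll, log(0.999))
  # the opposite-modality model is maximally wrong on incongruent trials
  inc <- trials[trials$visual != trials$auditory, ]
  ll_op <- choice_model_loglik(choice_model("opposite_modality"), inc)
  expect_equal(ll_op, log(0.001))
  # unbiased random licking
  ll_rb <- choice_model_loglik(choice_model("random_bias", p_lick = 0.5),
                               trials)
  expect_equal(ll_rb, log(0.5))
  expect_error(choice_model_loglik(choice_model("random_bias"),
                                   trials[0, ]), "empty")
})

test_that("d-prime follows the clipped inverse-normal definition", {
  expect_equal(d_prime(0.7, 0.7), 0)
  expect_equal(d_prime(1, 0), qnorm(0.99) - qnorm(0.01))
  expect_equal(d_prime(0.9, 0.1), 2 * qnorm(0.9))
  # antisymmetry
  for (h in c(0.3, 0.6, 0.95)) {
    expect_equal(d_prime(h, 0.2), -d_prime(0.2, h))
  }
})

test_that("simulated sessions follow the generating model and seed", {
  ses1 <- make_session(lambda = 0, n = 60, seed = 9)
  expect_true(all(ses1$correct[!ses1$congruent] == 1L))
  ses2 <- make_session(lambda = 0.5, n = 400, seed = 9)
  expect_lt(abs(mean(ses2$correct[!ses2$congruent]) - 0.5), 0.08)
  expect_identical(make_session(seed = 5), make_session(seed = 5))
  expect_false(identical(make_session(seed = 5), make_session(seed = 6)))
})

test_that("moving averages and the consistency mask follow the rule", {
  # all-correct block: every curve 1, every trial consistent
  blk <- make_block(visual = rep(c(1, 0, 1, 0), 10),
                    auditory = rep(c(1, 0, 0, 1), 10),
                    lick = rep(c(1, 0, 1, 0), 10))
  mam <- moving_average_performance(blk, window = 5)
  expect_true(all(unlist(mam$curves) == 1))
  expect_true(all(mam$consistent))
  # failing all incongruent trials: incongruent curves 0, nothing consistent
  blk2 <- make_block(visual = rep(c(1, 0, 1, 0), 10),
                     auditory = rep(c(1, 0, 0, 1), 10),
                     lick = rep(c(1, 0, 0, 1), 10))
  mam2 <- moving_average_performance(blk2, window = 5)
  expect_true(all(mam2$curves$go_incongruent == 0, na.rm = TRUE))
  expect_false(any(mam2$consistent))
  # windowed-mean oracle on an alternating pattern
  v <- rep(1, 30); a <- rep(0, 30)      # all incongruent go trials
  lick <- rep(c(1L, 0L), 15)
  blk3 <- make_block(v, a, lick)
  mam3 <- moving_average_performance(blk3, window = 21)
  oracle <- vapply(seq_len(30), function(i) {
    lo <- max(1, i - 10); hi <- min(30, i + 10)
    mean(blk3$correct[lo:hi])
  }, numeric(1))
  expect_equal(mam3$curves$go_incongruent, oracle)
  # strict threshold flips borderline trials
  mam3s <- moving_average_performance(blk3, window = 21, strict = TRUE)
  border <- which(abs(oracle - 0.5) < 1e-12)
  expect_true(all(!mam3s$consistent[border]))
})

test_that("Monte-Carlo consistency null matches exact enumeration", {
  set.seed(11)
  v <- rbinom(30, 1, 0.5)
  a <- rbinom(30, 1, 0.5)
  # force some incongruent trials but no more than 12
  inc <- which(v != a)
  if (length(inc) > 12) {
    a[inc[-(1:12)]] <- v[inc[-(1:12)]]
  }
  lick <- ifelse(v != a, rbinom(30, 1, 0.7), v)
  blk <- make_block(v, a, lick)
  exact <- consistency_null_exact(blk, window = 9)
  mc <- consistency_null_probability(blk, n_sim = 4000, seed = 3,
                                     window = 9)
  se <- sqrt(exact$p_null * (1 - exact$p_null) / 4000)
  expect_lt(abs(mc$p_null - exact$p_null), 3 * se + 1e-12)
  # monotonicity: probability cannot increase with a higher observed count
  cnt <- function(session, window) {
    sum(moving_average_performance(session, window)$consistent)
  }
  expect_error(consistency_null_probability(
    make_block(c(1, 1), c(1, 1), c(1, 1)), n_sim = 10),
    "no incongruent")
})

test_that("model recovery prefers the generating context-aware model", {
  ses <- make_session(lambda = 0.1, n = 250, seed = 21)
  mam <- moving_average_performance(ses)
  sub <- ses[mam$consistent & !ses$congruent, ]
  ll_gen <- choice_model_loglik(
    choice_model("context_aware_lapse", lambda = 0.1), sub)
  ll_opp <- choice_model_loglik(choice_model("opposite_modality"), sub)
  expect_gt(ll_gen, ll_opp)
  # lapse recovery within tolerance at moderate n
  fit <- fit_lapse(ses[!ses$congruent, ])
  expect_lt(abs(fit$lambda - 0.1), 0.05)
})
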