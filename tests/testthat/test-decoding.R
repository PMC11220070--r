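test_that("DV angles satisfy the metric identities", {
  d1 <- c(1, 0, 0); d2 <- c(0, 1, 0)
  expect_equal(dv_angle(d1, d1), 0)
  expect_equal(dv_angle(d1, d2), 90)
  expect_equal(dv_angle(d1, -d1), 180)
  expect_equal(dv_angle(d1, d2), dv_angle(d2, d1))
  expect_equal(dv_angle(3.7 * d1, 0.2 * d2), dv_angle(d1, d2))
  expect_error(dv_angle(d1, c(0, 0, 0)), "zero")
})

test_that("the 2-D subspace construction is the Gram-Schmidt plane", {
  d1 <- c(1, 0, 0, 0)
  d2 <- c(1, 1, 0, 0) / sqrt(2)          # 45 degrees to d1
  sp <- subspace_2d(d1, d2)
  expect_equal(sp$axis1, d1)
  expect_equal(sp$axis2, c(0, 1, 0, 0))
  expect_equal(as.numeric(sp$project(d1)), c(1, 0))
  co <- sp$project(rbind(d2))
  expect_equal(as.numeric(co), c(cos(pi / 4), sin(pi / 4)))
  expect_error(subspace_2d(d1, 2 * d1), "parallel")
})

test_that("planted separable signal decodes perfectly, shuffles at chance", {
  fx <- make_tensor(gamma = 1, n = 40, noise = 0.5)
  stim_tp <- which(fx$tensor$time_s > 0.5 & fx$tensor$time_s < 2)[1:3]
  ds <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                               folds = 5, timepoints = stim_tp)
  expect_true(all(ds$accuracy > 0.95))
  expect_equal(colSums(ds$dv_unit^2), rep(1, length(stim_tp)))
  set.seed(13)
  shuffled <- sample(fx$tensor$trials$visual)
  ds_sh <- fit_timepoint_decoders(fx$tensor, shuffled, folds = 5,
                                  timepoints = stim_tp)
  expect_true(all(abs(ds_sh$accuracy - 0.5) < 0.2))
  # class below the minimum trial count is refused, not silently fit
  few <- c(rep(1L, 9), rep(0L, dim(fx$tensor$rates)[1] - 9))
  ds_few <- fit_timepoint_decoders(fx$tensor, few, min_per_class = 10)
  expect_false(ds_few$available)
})

test_that("angle recovery matches the planted geometry", {
  # stimulus decoders are conditioned on the other modality being fixed
  # (single-modality-style trials): with correlated embeddings an
  # unconditioned discriminant whitens away the other stimulus variance
  # and biases the angle toward 90 degrees
  est_angle <- function(angle_va, seed) {
    fx <- make_tensor(n = 100, noise = 1, angle_va = angle_va, seed = seed)
    tens <- fx$tensor
    early <- which(tens$time_s >= 0.25 & tens$time_s < 0.75)
    dvv <- rowMeans(fit_timepoint_decoders(
      tens, tens$trials$visual, subset = tens$trials$auditory == 0,
      timepoints = early, folds = 5)$dv)
    dva <- rowMeans(fit_timepoint_decoders(
      tens, tens$trials$auditory, subset = tens$trials$visual == 0,
      timepoints = early, folds = 5)$dv)
    dv_angle(dvv, dva)
  }
  expect_lt(abs(est_angle(90, 17) - 90), 10)
  expect_lt(abs(est_angle(60, 18) - 60), 10)
})

test_that("cross-time projection separates classes along the early DV", {
  fx <- make_tensor(gamma = 0, n = 40, noise = 0.5)
  tens <- fx$tensor
  ds <- fit_timepoint_decoders(tens, tens$trials$visual, folds = 5)
  pr <- project_activity(ds, tens, train_window = c(0.25, 0.75),
                         subset = fx$session$context == "visual")
  v <- tens$trials$visual[fx$session$context == "visual"]
  stim <- pr$time_s > 0.5 & pr$time_s < 2
  gap <- mean(pr$y[v == 1, stim]) - mean(pr$y[v == 0, stim])
  expect_gt(gap, 1)
  # the projection of the DV direction itself is its norm, zero stays zero
  unitx <- matrix(0, 1, dim(tens$rates)[2]); unitx[1, ] <- pr$dv
  sp <- subspace_2d(pr$dv, rnorm(length(pr$dv)))
  expect_equal(as.numeric(unitx %*% pr$dv), 1)
})

test_that("block averaging finds the autocorrelation zero-crossing", {
  time_s <- seq(0, 3, by = 0.01)
  set.seed(19)
  white <- rnorm(length(time_s))
  ba <- block_average(white, time_s, range = c(0.6, 3))
  expect_true(ba$from_autocorr)
  expect_lt(ba$width, 0.05)              # white noise decorrelates at lag 1
  const <- rep(1, length(time_s))
  ba2 <- block_average(const, time_s, range = c(0.6, 3))
  expect_true(ba2$fallback)
  expect_equal(ba2$width, 0.6)
  # fixed paper-style width gives 4 blocks on [0.6, 3)
  ba3 <- block_average(white, time_s, width = 0.6, range = c(0.6, 3))
  expect_identical(ba3$n_blocks, 4L)
  expect_equal(ba3$block_start, c(0.6, 1.2, 1.8, 2.4))
})

test_that("suppression metric is zero for identical series, positive under gating", {
  fx <- make_tensor(gamma = 0, n = 50, noise = 0.8)
  ses <- fx$session
  rel <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                                subset = ses$context == "visual", folds = 5)
  irr <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                                subset = ses$context == "auditory",
                                folds = 5)
  sp_same <- suppression_metric(rel, rel)
  expect_true(all(sp_same$difference == 0))
  sp <- suppression_metric(rel, irr)
  expect_true(sp$available)
  expect_identical(length(sp$block_difference), 4L)
  expect_true(all(sp$block_difference > 0))
  unavailable <- structure(list(available = FALSE),
                           class = "decoder_series")
  expect_false(suppression_metric(rel, unavailable)$available)
})

test_that("chance level sits near 0.5 and below true-signal accuracy", {
  fx <- make_tensor(gamma = 1, n = 60, noise = 1)
  tp <- which(fx$tensor$time_s > 0.5 & fx$tensor$time_s < 1.5)[1:2]
  ch <- chance_level(fx$tensor, fx$tensor$trials$visual, n_shuffles = 8,
                     folds = 5, timepoints = tp)
  expect_true(all(abs(ch$mean - 0.5) < 0.06))
  expect_true(all(ch$threshold > ch$mean))
  ds <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                               folds = 5, timepoints = tp)
  expect_true(all(ds$accuracy > ch$threshold))
})

test_that("edge-vs-middle context scheme flags drift but not stationary signal", {
  fx <- make_tensor(gamma = 1, n = 60, noise = 1, seed = 23)
  tens <- fx$tensor
  ctx <- as.integer(fx$session$context == "auditory")
  ew <- fit_context_decoder_edgewise(tens, ctx)
  expect_true(ew$available)
  # stationary planted context: directions statistically indistinguishable
  expect_gt(ew$p, 0.05)
  # planted linear drift with no context signal: edge-trained inflated
  spec0 <- population_spec(
    n_neurons = 24, dt = 0.25, noise_sd = 1,
    gains = c(visual = 4, auditory = 4, context = 0, decision = 3))
  drift_tens <- generate_population(spec0, fx$session, seed = 29)
  n_tr <- dim(drift_tens$rates)[1]
  drift <- seq(-2, 2, length.out = n_tr)
  dirs <- matrix(rnorm(dim(drift_tens$rates)[2]), ncol = 1)
  dirs <- dirs / sqrt(sum(dirs^2))
  for (j in seq_len(dim(drift_tens$rates)[2])) {
    drift_tens$rates[, j, ] <- drift_tens$rates[, j, ] + drift * dirs[j] * 3
  }
  drift_tens <- zscore_baseline(drift_tens)
  ew_d <- fit_context_decoder_edgewise(drift_tens, ctx)
  # under linear drift the two train-test directions disagree strongly:
  # testing at the session edges rides the drift separation while testing
  # in the middle does not, so the scheme flags a large asymmetry
  expect_gt(abs(mean(ew_d$accuracy_edge) - mean(ew_d$accuracy_middle)),
            0.15)
  expect_lt(ew_d$p, 0.05)
})
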