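test_that("relevance contrast flags planted suppression and partitions", {
  fx <- make_tensor(gamma = 0, n = 60, neurons = 20, noise = 0.8,
                    preset = "disjoint")
  rc <- relevance_contrast(fx$tensor, window = c(1.5, 2))
  expect_true(all(table(rc$modality, rc$signal) == 20))
  defined <- !is.na(rc$flag)
  expect_true(all(rc$flag[defined] %in%
                    c("lower", "higher", "unmodulated")))
  # no suppression and no context signal -> (almost) nothing flagged
  ses1 <- make_session(lambda = 0, n = 60, seed = 11)
  spec1 <- population_spec(
    n_neurons = 16, dt = 0.25, noise_sd = 2,
    gains = c(visual = 4, auditory = 4, context = 0, decision = 0))
  t1 <- zscore_baseline(generate_population(spec1, ses1, seed = 12))
  rc1 <- relevance_contrast(t1)
  frac_mod <- mean(rc1$flag != "unmodulated", na.rm = TRUE)
  expect_lt(frac_mod, 0.25)
})

test_that("predictive R2 is near 1 for a linear neuron and negative for noise", {
  set.seed(41)
  n_tr <- 60; n_t <- 6
  choice <- rbinom(n_tr, 1, 0.5)
  rates <- array(rnorm(n_tr * 2 * n_t, 0, 1), c(n_tr, 2, n_t))
  for (k in seq_len(n_t)) rates[, 1, k] <- 2 * choice + 1  # noiseless
  tens <- population_tensor(rates, seq(0, 1, length.out = n_t),
                            data.frame(choice = choice))
  ve <- variance_explained(tens, data.frame(choice = choice), folds = 5)
  expect_true(all(ve$r2[1, ] > 0.99))
  expect_true(all(is.na(ve$r2[2, ]) | ve$r2[2, ] < 0.2))
  expect_true(mean(ve$r2_raw[2, ] <= 0) > 0.5)   # noise: no predictive fit
  expect_true(all(ve$best_neuron == 1L))
  # constant predictor is dropped with a message
  expect_message(
    variance_explained(tens, data.frame(choice = choice,
                                        cst = rep(1, n_tr)), folds = 5),
    "constant")
})

test_that("relevant-stimulus model explains more variance than irrelevant", {
  # imperfect behaviour decorrelates choice from the relevant stimulus;
  # with a perfectly performing agent the two would be collinear
  ses <- simulate_behavior(
    choice_model("context_aware_lapse", lambda = 0.2),
    data.frame(context = c("visual", "auditory"), n_trials = c(60, 60)),
    seed = 7)
  spec <- population_spec(n_neurons = 20, dt = 0.25, noise_sd = 1,
                          suppression_gamma = 0, embed_seed = 7)
  tens <- zscore_baseline(generate_population(spec, ses, seed = 8))
  vis_ctx <- ses$context == "visual"
  cmp <- compare_variance_models(
    tens, choice = ses$lick, relevant = ses$visual,
    irrelevant = ses$auditory, subset = vis_ctx, folds = 5)
  expect_gt(cmp$excess, 0)
  expect_lt(cmp$p, 0.05)
})

test_that("modality and context indices behave as planted", {
  fx <- make_tensor(gamma = 0, n = 80, neurons = 20, noise = 0.8,
                    preset = "disjoint")
  tens <- fx$tensor
  early <- which(tens$time_s >= 0.25 & tens$time_s < 0.75)
  dvv <- rowMeans(fit_timepoint_decoders(
    tens, tens$trials$visual, subset = tens$trials$auditory == 0,
    timepoints = early, folds = 5)$dv)
  dva <- rowMeans(fit_timepoint_decoders(
    tens, tens$trials$auditory, subset = tens$trials$visual == 0,
    timepoints = early, folds = 5)$dv)
  mi <- modality_index(dvv, dva)
  expect_identical(mi, dvv - dva)
  # antisymmetry under swapping the modalities
  expect_identical(modality_index(dva, dvv), -mi)
  # disjoint preset: visual block 1-5, auditory block 6-10 out of 20
  expect_true(mean(rank(-mi)[1:5]) < mean(rank(-mi)[6:10]))
  # context index: planted tonic context signal has block 11-15 positive
  ci <- context_index(tens, "trial")
  expect_true(all(ci[11:15] > 0.5))
  expect_lt(max(abs(ci[c(1:10, 16:20)])), 0.5)
  # context-blind neurons: zero-gain spec
  ses0 <- fx$session
  spec0 <- population_spec(
    n_neurons = 8, dt = 0.5,
    gains = c(visual = 2, auditory = 2, context = 0, decision = 0))
  t0 <- zscore_baseline(generate_population(spec0, ses0, seed = 3))
  # signal-wise averaging removes the go/no-go mix imbalance
  ci0 <- (context_index(t0, "trial", signal = "go") +
            context_index(t0, "trial", signal = "nogo")) / 2
  expect_lt(max(abs(ci0)), 0.25)
  # window presets resolve to the documented intervals
  expect_error(context_index(tens, "nonsense"))
})

test_that("modality-context correlation is negative under mutual suppression", {
  # build per-neuron indices directly: strong modality tuning with
  # context modulation aligned to the preferred modality
  set.seed(43)
  n <- 40
  mi <- sort(rnorm(n, 0, 1), decreasing = TRUE)
  ci <- 0.8 * mi + rnorm(n, 0, 0.3)      # more active in preferred context
  out <- modality_context_correlation(mi, ci)
  expect_lt(out$r, -0.5)                 # rank is descending: r < 0
  expect_lt(out$p, 1e-4)
  # raw-index correlation has the same sign, comparable magnitude
  out_raw <- modality_context_correlation(mi, ci, use_rank = FALSE)
  expect_gt(out_raw$r, 0.5)              # raw index correlates positively
  expect_equal(abs(out$r), abs(out_raw$r), tolerance = 0.2)
  # trimming extreme ranks does not change the conclusion
  out_trim <- modality_context_correlation(mi, ci, trim = 4)
  expect_lt(out_trim$r, -0.5)
  # degenerate variance is flagged
  deg <- modality_context_correlation(mi, rep(0, n))
  expect_true(deg$degenerate)
})
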