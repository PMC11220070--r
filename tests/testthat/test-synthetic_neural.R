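test_that("planted angles are exact by construction", {
  spec <- population_spec(n_neurons = 30)
  expect_equal(planted_angle(spec, "visual", "auditory"), 90)
  expect_equal(planted_angle(spec, "visual", "visual"), 0)
  spec60 <- population_spec(n_neurons = 30, angle_va = 60)
  expect_equal(planted_angle(spec60, "visual", "auditory"), 60)
  specd <- population_spec(n_neurons = 40, preset = "disjoint")
  expect_equal(planted_angle(specd, "context", "decision"), 90)
  expect_error(population_spec(preset = "disjoint", angle_va = 60),
               "orthogonal")
})

test_that("generation is seed-reproducible and respects the noise model", {
  ses <- make_session(lambda = 0, n = 20, seed = 2)
  spec <- population_spec(n_neurons = 10, dt = 0.5)
  t1 <- generate_population(spec, ses, seed = 4)
  t2 <- generate_population(spec, ses, seed = 4)
  expect_identical(t1$rates, t2$rates)
  t3 <- generate_population(spec, ses, seed = 5)
  expect_false(identical(t1$rates, t3$rates))
  # poisson mode produces non-negative count-derived rates
  specp <- population_spec(n_neurons = 10, dt = 0.5,
                           noise = "poisson_counts")
  tp <- generate_population(specp, ses, seed = 4)
  expect_true(all(tp$rates >= 0))
})

test_that("zero gains produce chance-level decoding", {
  ses <- make_session(lambda = 0, n = 30, seed = 3)
  spec <- population_spec(
    n_neurons = 16, dt = 0.5,
    gains = c(visual = 0, auditory = 0, context = 0, decision = 0))
  tens <- zscore_baseline(generate_population(spec, ses, seed = 6))
  ds <- fit_timepoint_decoders(tens, tens$trials$visual, folds = 5,
                               timepoints = c(4L, 7L))
  expect_true(all(abs(ds$accuracy - 0.5) < 0.2))
})

test_that("suppression gamma controls the relevant-irrelevant asymmetry", {
  fx1 <- make_tensor(gamma = 1, n = 50, noise = 0.8)
  fx0 <- make_tensor(gamma = 0, n = 50, noise = 0.8)
  late <- which(fx1$tensor$time_s > 1.5 & fx1$tensor$time_s < 3)
  acc_of <- function(fx) {
    ses <- fx$session
    rel <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                                  subset = ses$context == "visual",
                                  folds = 5, timepoints = late)
    irr <- fit_timepoint_decoders(fx$tensor, fx$tensor$trials$visual,
                                  subset = ses$context == "auditory",
                                  folds = 5, timepoints = late)
    c(rel = mean(rel$accuracy), irr = mean(irr$accuracy))
  }
  a1 <- acc_of(fx1); a0 <- acc_of(fx0)
  # gamma = 1: symmetric construction, no appreciable difference
  expect_lt(abs(a1["rel"] - a1["irr"]), 0.12)
  # gamma = 0: irrelevant stimulus decays to chance while relevant stays
  expect_gt(a0["rel"], 0.9)
  expect_lt(a0["irr"], 0.65)
})
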