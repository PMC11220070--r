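# Shared fixtures, generated in code.

# a small two-block session with known structure
make_session <- function(lambda = 0.1, n = 80, seed = 42) {
  simulate_behavior(
    choice_model("context_aware_lapse", lambda = lambda),
    data.frame(context = c("visual", "auditory"), n_trials = c(n, n)),
    seed = seed)
}

# a deterministic session with hand-set outcomes for moving-average tests
make_block <- function(visual, auditory, lick, context = "visual") {
  target <- if (identical(context, "visual")) visual else auditory
  data.frame(
    trial_index = seq_along(visual), block = 1L, context = context,
    visual = visual, auditory = auditory,
    congruent = visual == auditory, target = target, lick = lick,
    correct = as.integer(lick == target),
    stringsAsFactors = FALSE)
}

# small high-SNR population for decoding tests
make_tensor <- function(gamma = 1, n = 60, neurons = 24, noise = 1,
                        preset = "mixed", angle_va = 90, seed = 7,
                        dt = 0.25, decision_persist = FALSE) {
  ses <- simulate_behavior(
    choice_model("correct_modality"),
    data.frame(context = c("visual", "auditory"), n_trials = c(n, n)),
    seed = seed)
  spec <- population_spec(
    n_neurons = neurons, dt = dt, noise_sd = noise,
    suppression_gamma = gamma, preset = preset, angle_va = angle_va,
    decision_persist = decision_persist, embed_seed = seed)
  list(spec = spec, session = ses,
       tensor = zscore_baseline(generate_population(spec, ses,
                                                    seed = seed + 1)))
}
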