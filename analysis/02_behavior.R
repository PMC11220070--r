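#!/usr/bin/env Rscript
# Behavioural analysis on simulated context-switching sessions: moving
# average performance curves per trial type, consistent/exploratory
# segmentation, the Monte-Carlo consistency null, choice-model comparison
# by mean log-likelihood on consistent incongruent trials, and d'.
#
# Usage: Rscript analysis/02_behavior.R [seed]

library(ctxgate)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- file.path("results", "02_behavior")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# a competent but imperfect agent: context-aware with a 10% lapse
gen <- choice_model("context_aware_lapse", lambda = 0.1)
session <- simulate_behavior(
  gen, data.frame(context = c("visual", "auditory"),
                  n_trials = c(120L, 120L)), seed = seed)
write_trial_table(session, file.path(out_dir, "session.csv"))

mam <- moving_average_performance(session, window = 21L)
write.csv(cbind(trial_index = session$trial_index, mam$curves,
                consistent = mam$consistent),
          file.path(out_dir, "consistency_curves.csv"), row.names = FALSE)
cat(sprintf("consistent trials: %d / %d (%.1f%%)\n",
            sum(mam$consistent), nrow(session),
            100 * mean(mam$consistent)))

null_tab <- consistency_null_probability(session, n_sim = 100000L,
                                         seed = seed + 1L)
write.csv(null_tab, file.path(out_dir, "consistency_null.csv"),
          row.names = FALSE)
cat("context-unaware null probabilities per block:\n")
print(null_tab[, c("block", "context", "observed_consistent", "p_null")])

# choice model comparison on consistent incongruent trials
sub <- session[mam$consistent & !session$congruent, ]
models <- list(
  correct_modality = choice_model("correct_modality"),
  opposite_modality = choice_model("opposite_modality"),
  random_bias = choice_model("random_bias", p_lick = mean(sub$lick)),
  context_aware_lapse = choice_model("context_aware_lapse",
                                     lambda = fit_lapse(sub)$lambda)
)
ll <- vapply(models, choice_model_loglik, numeric(1), trials = sub)
write.csv(data.frame(model = names(ll), mean_loglik = ll),
          file.path(out_dir, "choice_models.csv"), row.names = FALSE)
cat("mean log-likelihoods (consistent incongruent trials):\n")
print(round(ll, 4))

# d' per context block
dp <- do.call(rbind, lapply(split(session, session$block), function(b) {
  hits <- mean(b$lick[b$target == 1] == 1)
  fas <- mean(b$lick[b$target == 0] == 1)
  data.frame(block = b$block[1], context = b$context[1],
             hit_rate = hits, fa_rate = fas, d_prime = d_prime(hits, fas))
}))
write.csv(dp, file.path(out_dir, "d_prime.csv"), row.names = FALSE)
cat("d' by block:\n"); print(dp)
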