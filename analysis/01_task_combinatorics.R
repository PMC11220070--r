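#!/usr/bin/env Rscript
# Enumerate the five-trial sequence space of the set-shifting task and
# tabulate its combinatorial structure: 1024 sequences per context, how
# many are congruent-only, and the 32-per-context unsolvable type (four
# congruent trials followed by an incongruent one, which no observer can
# answer above chance).

library(ctxgate)

out_dir <- file.path("results", "01_task")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ds <- build_dataset()
write_sequences(ds, file.path(out_dir, "sequences.csv"))

first <- ds[ds$trial_index == 1L, ]
per_ctx <- table(first$context)
unsolv <- tapply(!first$solvable, first$context, sum)
all_con <- tapply(ds$congruent, list(ds$context, ds$sequence_id), all)

summary_tab <- data.frame(
  context = names(per_ctx),
  n_sequences = as.integer(per_ctx),
  n_unsolvable = as.integer(unsolv[names(per_ctx)]),
  n_all_congruent = as.integer(rowSums(all_con))
)
write.csv(summary_tab, file.path(out_dir, "summary.csv"), row.names = FALSE)

cat("sequence space:\n")
print(summary_tab)
cat(sprintf("total %d sequences, %.3f%% unsolvable\n",
            nrow(first), 100 * mean(!first$solvable)))
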