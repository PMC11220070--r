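#!/usr/bin/env Rscript
# Representation and weight-structure analyses of the trained networks:
# DV angles of the hidden representation, suppression of the irrelevant
# stimulus in input-weight projections, recurrent-matrix block structure
# under modality-index ordering, decision persistence across trials, and
# the pooled context-index / modality-rank correlation.
#
# Expects results/04_rnn/models.rds from analysis/04_rnn_training.R.

library(ctxgate)

in_path <- file.path("results", "04_rnn", "models.rds")
stopifnot(file.exists(in_path))
models <- readRDS(in_path)
out_dir <- file.path("results", "05_rnn_analysis")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

passing <- Filter(function(m) m$performance > 0.9, models)
cat(sprintf("%d/%d models pass the 0.9 filter\n",
            length(passing), length(models)))

# DV angles (mean over passing models, t test against 90 degrees)
ang <- t(vapply(passing, function(m) rnn_dv_angles(m), numeric(4)))
ang_stats <- do.call(rbind, lapply(colnames(ang), function(p) {
  tt <- t.test(ang[, p], mu = 90)
  data.frame(pair = p, mean_deg = mean(ang[, p]),
             t = unname(tt$statistic), p_value = tt$p.value)
}))
write.csv(ang_stats, file.path(out_dir, "dv_angles.csv"),
          row.names = FALSE)
cat("DV angles vs 90 degrees:\n"); print(ang_stats)

# suppression of the irrelevant stimulus in input-weight projections
sup <- t(vapply(passing, function(m) {
  pr <- rnn_stimulus_projection(m)
  c(visual = pr$visual$suppression, auditory = pr$auditory$suppression)
}, numeric(2)))
write.csv(data.frame(seed = vapply(passing, `[[`, numeric(1), "seed"),
                     sup),
          file.path(out_dir, "input_projection_suppression.csv"),
          row.names = FALSE)
cat(sprintf("mean relevant-irrelevant projection difference: %.3f\n",
            mean(sup)))

# recurrent-matrix block structure across powers 2..6
blocks <- do.call(rbind, lapply(passing, function(m) {
  cbind(seed = m$seed, analyze_weights(m)$block_stats)
}))
agg <- aggregate(cbind(diag_mean, offdiag_mean) ~ power, blocks, mean)
write.csv(agg, file.path(out_dir, "recurrent_blocks.csv"),
          row.names = FALSE)
cat("recurrent block means by power:\n"); print(agg)

# pooled context-index / modality-rank correlation
pooled <- rnn_pooled_correlation(models, min_performance = 0.9)
write.csv(data.frame(r = pooled$r, t = pooled$t, p = pooled$p,
                     n = pooled$n, n_models = pooled$n_models),
          file.path(out_dir, "pooled_correlation.csv"), row.names = FALSE)
cat(sprintf("pooled context-index vs modality-rank: r = %.3f (n = %d units, %d models)\n",
            pooled$r, pooled$n, pooled$n_models))

# performance regression across all models (no filter)
reg <- rnn_performance_regression(models)
write.csv(reg$data, file.path(out_dir, "performance_regression.csv"),
          row.names = FALSE)
cat(sprintf("performance vs suppression: slope %.3f, t = %.2f, p = %.2g\n",
            reg$slope, reg$t, reg$p))

# decision persistence for one example passing model
if (length(passing) >= 1) {
  ds <- rnn_decision_persistence(passing[[1]])
  if (ds$available) {
    write.csv(data.frame(step = ds$time_s, accuracy = ds$accuracy),
              file.path(out_dir, "decision_persistence.csv"),
              row.names = FALSE)
  }
}
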