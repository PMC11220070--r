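#' Initialize a gateless recurrent network
#'
#' Weights are drawn uniformly from \[-1/sqrt(h), 1/sqrt(h)\] (the standard
#' initialization for ungated recurrent layers). The network has stimulus
#' input weights U (hidden x 4, one-hot visual go/no-go and auditory
#' go/no-go), reward input weights V (hidden x 2, one-hot success/error),
#' recurrent weights F (hidden x hidden), and output weights D (2 x
#' hidden); the elementwise nonlinearity is tanh and there are no gates or
#' bias terms.
#'
#' @param hidden Hidden layer size.
#' @param seed Integer seed fixing the initial weights.
#' @return An object of class `rnn_model`.
#' @export
rnn_init <- function(hidden = 30L, seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  sc <- 1 / sqrt(hidden)
  m <- list(
    U = matrix(stats::runif(hidden * 4L, -sc, sc), hidden, 4L,
               dimnames = list(NULL, c("visual_go", "visual_nogo",
                                       "auditory_go", "auditory_nogo"))),
    V = matrix(stats::runif(hidden * 2L, -sc, sc), hidden, 2L,
               dimnames = list(NULL, c("success", "error"))),
    F = matrix(stats::runif(hidden * hidden, -sc, sc), hidden, hidden),
    D = matrix(stats::runif(2L * hidden, -sc, sc), 2L, hidden,
               dimnames = list(c("go", "nogo"), NULL)),
    hidden = hidden, seed = seed, trained = FALSE
  )
  .Random.seed_restore(old)
  class(m) <- "rnn_model"
  m
}

#' Train the recurrent network on the full sequence dataset
#'
#' Trains on all 2048 five-trial sequences with ADAM; the loss is the
#' cross-entropy of the softmax-ed output at the final trial's decision
#' step against the contextual target. One epoch visits every sequence
#' once in random minibatches; the reward input is a discrete consequence
#' of the network's own decisions and is not differentiated through.
#' Training is deterministic given `seed`.
#'
#' @param hidden Hidden layer size.
#' @param epochs Training epochs.
#' @param lr ADAM learning rate (initial value of the decayed schedule).
#' @param batch_size Sequences per gradient update.
#' @param lr_decay Decay the learning rate linearly to zero over the
#'   later part of training (constant for the first `decay_start`
#'   fraction of epochs).
#' @param decay_start Fraction of epochs trained at the full rate before
#'   the linear decay begins.
#' @param seed Seed for initialization and batch shuffling.
#' @param record_every Learning-curve sampling interval (epochs).
#' @return A trained `rnn_model` with `curve` (per-epoch loss and
#'   fraction-correct on all / congruent / incongruent final trials) and
#'   `performance` (final fraction-correct over all 2048 final trials).
#' @export
rnn_train <- function(hidden = 30L, epochs = 5000L, lr = 1e-4,
                      batch_size = 1L, lr_decay = TRUE, decay_start = 0.5,
                      seed = 1L, record_every = 50L) {
  m <- rnn_init(hidden, seed)
  fit <- rnn_train_cpp(m$U, m$V, m$F, m$D, as.integer(epochs), lr,
                       as.integer(record_every), as.integer(batch_size),
                       as.integer(seed), lr_decay, decay_start, FALSE)
  m$U <- fit$U; m$V <- fit$V; m$F <- fit$F; m$D <- fit$D
  dimnames(m$U) <- list(NULL, c("visual_go", "visual_nogo",
                                "auditory_go", "auditory_nogo"))
  dimnames(m$D) <- list(c("go", "nogo"), NULL)
  m$curve <- fit$curve
  m$performance <- fit$final_acc_all
  m$performance_congruent <- fit$final_acc_congruent
  m$performance_incongruent <- fit$final_acc_incongruent
  m$epochs <- epochs; m$lr <- lr; m$batch_size <- batch_size
  m$lr_decay <- lr_decay; m$decay_start <- decay_start
  m$trained <- TRUE
  m
}

#' Train a population of networks with fixed per-model seeds
#'
#' @param n_models Number of models.
#' @param seed0 Seed of the first model; model k uses `seed0 + k - 1`.
#' @param ... Passed to [rnn_train()].
#' @return List of `rnn_model`s (models whose loss diverged are dropped
#'   with a message).
#' @export
rnn_train_models <- function(n_models = 10L, seed0 = 1L, ...) {
  models <- list()
  for (k in seq_len(n_models)) {
    m <- rnn_train(seed = seed0 + k - 1L, ...)
    if (any(!is.finite(m$curve$loss))) {
      message(sprintf("model seed %d diverged; discarded", m$seed))
      next
    }
    models[[length(models) + 1L]] <- m
  }
  models
}

#' @export
print.rnn_model <- function(x, ...) {
  if (x$trained) {
    cat(sprintf(
      "rnn_model: %d hidden units, seed %d, trained %d epochs; performance %.3f (congruent %.3f, incongruent %.3f)\n",
      x$hidden, x$seed, x$epochs, x$performance,
      x$performance_congruent, x$performance_incongruent))
  } else {
    cat(sprintf("rnn_model: %d hidden units, seed %d (untrained)\n",
                x$hidden, x$seed))
  }
  invisible(x)
}

#' Roll the network over explicit sequences
#'
#' Runs the deterministic 75-step rollout (5 trials x 15 steps) for each
#' sequence and returns hidden states, outputs, per-trial decisions and
#' rewards.
#'
#' @param model An `rnn_model`.
#' @param dataset A sequence table from [build_dataset()] /
#'   [enumerate_sequences()], or `NULL` for the full dataset.
#' @return List with `hidden` (sequences x units x 75 array), `output`
#'   (sequences x 2 x 75), `decision`, `correct` (sequences x 5),
#'   `codes` (the [sequence_codes()] of the dataset), `step_time`
#'   (global step index 1..75), and the per-trial decision steps
#'   `decision_steps`.
#' @export
rnn_run <- function(model, dataset = NULL) {
  if (is.null(dataset)) dataset <- build_dataset()
  codes <- sequence_codes(dataset)
  out <- rnn_run_cpp(model$U, model$V, model$F, model$D,
                     codes$stim, codes$context)
  clock <- task_clock()
  dec_steps <- (seq_len(clock$trials_per_sequence) - 1L) *
    clock$steps_per_trial + clock$decision_step
  list(hidden = aperm(out$hidden, c(2L, 1L, 3L)),
       output = aperm(out$output, c(2L, 1L, 3L)),
       decision = out$decision, correct = out$correct,
       codes = codes, step_time = seq_len(dim(out$hidden)[3]),
       decision_steps = dec_steps)
}

#' Hidden-state tensor view of a rollout
#'
#' Packs the hidden states of [rnn_run()] as a `population_tensor`
#' (sequences as trials, hidden units as neurons, global steps as the time
#' axis) so the population decoding and geometry toolkit applies directly
#' to the network.
#'
#' @param run Result of [rnn_run()].
#' @return A `population_tensor`; the trial table carries `context`
#'   (character), per-trial stimuli `visual1..5` / `auditory1..5`, and
#'   final-trial fields `visual`, `auditory`, `decision`.
#' @export
rnn_tensor <- function(run) {
  s <- run$codes$stim
  tr <- data.frame(context = ifelse(run$codes$context == 0L,
                                    "visual", "auditory"))
  for (t in 1:5) {
    tr[[paste0("visual", t)]] <- s[, t] %/% 2L
    tr[[paste0("auditory", t)]] <- s[, t] %% 2L
  }
  tr$visual <- tr$visual5
  tr$auditory <- tr$auditory5
  tr$decision <- run$decision[, 5L]
  tr$final_congruent <- run$codes$final_congruent
  population_tensor(run$hidden, run$step_time, tr,
                    meta = list(kind = "rnn_hidden"))
}

#' Epoch at which a learning-curve measure first crosses a level
#'
#' @param model A trained `rnn_model`.
#' @param level Threshold (fraction correct).
#' @param what Curve column (`"acc_congruent"`, `"acc_incongruent"`,
#'   `"acc_all"`).
#' @return Epoch of first crossing, or `Inf` when never crossed.
#' @export
first_crossing_epoch <- function(model, level = 0.9,
                                 what = "acc_congruent") {
  cv <- model$curve
  hit <- which(cv[[what]] >= level)
  if (length(hit) == 0L) Inf else cv$epoch[hit[1L]]
}

#' Per-signal modality indices of the hidden units
#'
#' Modality index of unit i for the go signal is
#' `U[i, visual_go] - U[i, auditory_go]`, and analogously for no-go: the
#' difference in stimulus drive between modalities. Ranks are assigned by
#' descending index separately per signal.
#'
#' @param model An `rnn_model`.
#' @return List with `go`, `nogo` (each: `index`, `rank`, `order`).
#' @export
rnn_modality_index <- function(model) {
  res <- list()
  for (sg in c("go", "nogo")) {
    idx <- model$U[, paste0("visual_", sg)] -
      model$U[, paste0("auditory_", sg)]
    res[[sg]] <- list(index = idx,
                      rank = rank(-idx, ties.method = "first"),
                      order = order(idx, decreasing = TRUE))
  }
  res
}

#' Per-unit context and modality index table for one network
#'
#' For each signal (go / no-go), units are indexed by the input-weight
#' modality index and by a context index: the mean hidden activity
#' difference between visual- and auditory-context sequences over
#' congruent trials of that signal (congruent-only, so the index is not a
#' trivial consequence of the relevant-signal reversal). Per-signal values
#' are then combined by averaging across signals at matched rank
#' positions.
#'
#' @param model A trained `rnn_model`.
#' @param run Optional precomputed [rnn_run()] on the full dataset.
#' @return Data frame with `rank`, `modality_index`, `context_index`
#'   (combined over signals), plus per-signal columns, and attribute
#'   `seed`.
#' @export
rnn_index_table <- function(model, run = NULL) {
  if (is.null(run)) run <- rnn_run(model)
  mi <- rnn_modality_index(model)
  clock <- task_clock()
  nh <- model$hidden
  s <- run$codes$stim
  ctx <- run$codes$context
  per_signal <- list()
  for (sg in c("go", "nogo")) {
    code <- if (sg == "go") 3L else 0L       # congruent go / congruent nogo
    acc <- matrix(0, nh, 2L)
    cnt <- c(0L, 0L)
    for (t in 1:5) {
      sel <- which(s[, t] == code)
      if (length(sel) == 0L) next
      steps <- (t - 1L) * clock$steps_per_trial + seq_len(clock$steps_per_trial)
      for (cx in 0:1) {
        ss <- sel[ctx[sel] == cx]
        if (length(ss) == 0L) next
        acc[, cx + 1L] <- acc[, cx + 1L] +
          apply(run$hidden[ss, , steps, drop = FALSE], 2, sum)
        cnt[cx + 1L] <- cnt[cx + 1L] + length(ss) * length(steps)
      }
    }
    cidx <- acc[, 1L] / cnt[1L] - acc[, 2L] / cnt[2L]
    per_signal[[sg]] <- list(context = cidx, modality = mi[[sg]])
  }
  ord_go <- per_signal$go$modality$order
  ord_ng <- per_signal$nogo$modality$order
  out <- data.frame(
    rank = seq_len(nh),
    modality_index = (per_signal$go$modality$index[ord_go] +
                        per_signal$nogo$modality$index[ord_ng]) / 2,
    context_index = (per_signal$go$context[ord_go] +
                       per_signal$nogo$context[ord_ng]) / 2,
    modality_index_go = per_signal$go$modality$index[ord_go],
    modality_index_nogo = per_signal$nogo$modality$index[ord_ng],
    context_index_go = per_signal$go$context[ord_go],
    context_index_nogo = per_signal$nogo$context[ord_ng]
  )
  attr(out, "seed") <- model$seed
  out
}

#' Pooled context-index / modality-rank correlation over models
#'
#' Pools the per-unit index tables of the models passing the performance
#' filter by averaging the combined context index at each modality-rank
#' position across models, then Pearson-correlates the averaged curve
#' against rank. (The per-position averaging is what makes the statistic
#' comparable across model populations: its degrees of freedom are the
#' rank positions, not the total unit count.)
#'
#' @param models List of trained `rnn_model`s.
#' @param min_performance Keep models with fraction-correct above this.
#' @return List with `r`, `t`, `p`, `n` (rank positions), `n_units`,
#'   `n_models`, `curve` (mean context index per rank), `table` (stacked
#'   per-model tables).
#' @export
rnn_pooled_correlation <- function(models, min_performance = 0.9) {
  keep <- Filter(function(m) m$performance > min_performance, models)
  if (length(keep) == 0L) {
    stop("no model passes the performance filter", call. = FALSE)
  }
  tabs <- lapply(keep, function(m) {
    tb <- rnn_index_table(m)
    tb$seed <- attr(tb, "seed")
    tb
  })
  tab <- do.call(rbind, tabs)
  curve <- tapply(tab$context_index, tab$rank, mean)
  rk <- as.integer(names(curve))
  ct <- modality_context_correlation(rk, as.numeric(curve),
                                     use_rank = TRUE, is_rank = TRUE)
  c(ct, list(n_units = nrow(tab), n_models = length(keep),
             curve = as.numeric(curve), table = tab))
}

#' Weight-structure analysis of a trained network
#'
#' Orders hidden units by the combined modality index (go and no-go
#' orderings averaged) and returns the recurrent matrix and its powers 2-6
#' in that order, each rescaled by its largest absolute entry. Powers of
#' the recurrent matrix approximate the cumulative effect of recurrence
#' from stimulus onset to the decision step. Block statistics summarize
#' the context-gating structure: means of the diagonal blocks
#' (within-modality) versus off-diagonal blocks (across-modality) under a
#' split of units into visual- and auditory-preferring halves.
#'
#' @param model A trained `rnn_model`.
#' @param powers Which matrix powers to return.
#' @return List with `order_go`, `order_nogo`, `ordered` (list of rescaled
#'   ordered matrices, averaged over the two signal orderings, named
#'   `F1`..), and `block_stats` (data frame per power: `diag_mean`,
#'   `offdiag_mean`).
#' @export
analyze_weights <- function(model, powers = 2:6) {
  mi <- rnn_modality_index(model)
  nh <- model$hidden
  mats <- list(F1 = model$F)
  Fk <- model$F
  for (k in seq_len(max(powers) - 1L)) {
    Fk <- Fk %*% model$F
    if ((k + 1L) %in% powers) mats[[paste0("F", k + 1L)]] <- Fk
  }
  half <- nh %/% 2L
  vis_half <- seq_len(half)
  aud_half <- seq(nh - half + 1L, nh)
  ordered <- list()
  stats_rows <- list()
  for (nm in names(mats)) {
    per_sig <- lapply(c("go", "nogo"), function(sg) {
      o <- mi[[sg]]$order
      m <- mats[[nm]][o, o]
      m / max(abs(m))
    })
    avg <- (per_sig[[1L]] + per_sig[[2L]]) / 2
    ordered[[nm]] <- avg
    dg <- mean(c(avg[vis_half, vis_half], avg[aud_half, aud_half]))
    od <- mean(c(avg[vis_half, aud_half], avg[aud_half, vis_half]))
    stats_rows[[nm]] <- data.frame(power = nm, diag_mean = dg,
                                   offdiag_mean = od,
                                   stringsAsFactors = FALSE)
  }
  list(order_go = mi$go$order, order_nogo = mi$nogo$order,
       ordered = ordered, block_stats = do.call(rbind, stats_rows))
}

#' Decision-vector angles of the network's hidden representation
#'
#' Decodes the task variables from the hidden states with the population
#' decoding toolkit and measures DV angles: visual versus auditory stimulus
#' at the first stimulus timestep of trial 1 (before recurrence mixes the
#' input), and context against visual, auditory and decision at the
#' final-trial decision step.
#'
#' @param model A trained `rnn_model`.
#' @param run Optional precomputed [rnn_run()].
#' @param lambda,folds,seed Decoder settings.
#' @return Named numeric vector of angles (degrees):
#'   `visual_auditory`, `context_visual`, `context_auditory`,
#'   `context_decision`.
#' @export
rnn_dv_angles <- function(model, run = NULL, lambda = 1e-3, folds = 10L,
                          seed = 1L) {
  if (is.null(run)) run <- rnn_run(model)
  tens <- rnn_tensor(run)
  clock <- task_clock()
  first_stim <- clock$stim_on
  dec_step <- run$decision_steps[5L]
  dv_of <- function(labels, step) {
    ds <- fit_timepoint_decoders(tens, labels, folds = folds,
                                 lambda = lambda, timepoints = step,
                                 seed = seed)
    stopifnot(ds$available)
    ds$dv[, 1L]
  }
  dv_v1 <- dv_of(tens$trials$visual1, first_stim)
  dv_a1 <- dv_of(tens$trials$auditory1, first_stim)
  dv_ctx <- dv_of(as.integer(tens$trials$context == "visual"), dec_step)
  dv_v5 <- dv_of(tens$trials$visual, dec_step)
  dv_a5 <- dv_of(tens$trials$auditory, dec_step)
  dv_dec <- dv_of(tens$trials$decision, dec_step)
  c(visual_auditory = dv_angle(dv_v1, dv_a1),
    context_visual = dv_angle(dv_ctx, dv_v5),
    context_auditory = dv_angle(dv_ctx, dv_a5),
    context_decision = dv_angle(dv_ctx, dv_dec))
}

#' Relevant/irrelevant hidden activity projected on stimulus input weights
#'
#' Projects trial-averaged hidden activity on each modality's normalized
#' input-weight difference (go minus no-go columns; for stimuli this is
#' the stimulus-subspace direction). Go and no-go trials are averaged
#' after sign alignment, separately for sequences where the modality is
#' relevant (its context) or irrelevant.
#'
#' @param model A trained `rnn_model`.
#' @param run Optional precomputed [rnn_run()].
#' @param trial Which trial of the sequence to analyze (default final).
#' @return List per modality: matrix with rows `relevant`, `irrelevant`
#'   and one column per within-trial step, plus `stim_steps`, and
#'   `suppression` (mean relevant minus irrelevant over stimulus steps).
#' @export
rnn_stimulus_projection <- function(model, run = NULL, trial = 5L) {
  if (is.null(run)) run <- rnn_run(model)
  clock <- task_clock()
  steps <- (trial - 1L) * clock$steps_per_trial +
    seq_len(clock$steps_per_trial)
  stim_steps <- seq(clock$stim_on, clock$stim_off)
  s <- run$codes$stim[, trial]
  ctx <- run$codes$context
  out <- list()
  for (m in c("visual", "auditory")) {
    u <- model$U[, paste0(m, "_go")] - model$U[, paste0(m, "_nogo")]
    u <- u / sqrt(sum(u^2))
    sig <- if (m == "visual") s %/% 2L else s %% 2L
    m_ctx <- if (m == "visual") 0L else 1L
    trace <- function(rel) {
      sel_ctx <- if (rel) ctx == m_ctx else ctx != m_ctx
      rows <- vapply(steps, function(st) {
        h <- run$hidden[, , st]
        y <- as.numeric(h %*% u)
        mean(y[sel_ctx & sig == 1L]) - mean(y[sel_ctx & sig == 0L])
      }, numeric(1))
      rows / 2
    }
    rel <- trace(TRUE); irr <- trace(FALSE)
    out[[m]] <- list(
      trace = rbind(relevant = rel, irrelevant = irr),
      stim_steps = stim_steps,
      suppression = mean(rel[stim_steps] - irr[stim_steps]))
  }
  out
}

#' Regression of performance on relevant-irrelevant activity difference
#'
#' Across models (no performance filter), regresses each model's overall
#' fraction-correct on its mean relevant-minus-irrelevant projected
#' activity difference (both modalities combined). A positive relationship
#' indicates that stronger context-gated suppression accompanies better
#' task execution.
#'
#' @param models List of trained `rnn_model`s.
#' @return List with `slope`, `t`, `p`, `r`, `n`, and the per-model data.
#' @export
rnn_performance_regression <- function(models) {
  dat <- do.call(rbind, lapply(models, function(m) {
    pr <- rnn_stimulus_projection(m)
    data.frame(seed = m$seed, performance = m$performance,
               act_diff = (pr$visual$suppression +
                             pr$auditory$suppression) / 2)
  }))
  fit <- stats::lm(act_diff ~ performance, data = dat)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       t = sm$coefficients[2L, "t value"],
       p = sm$coefficients[2L, "Pr(>|t|)"],
       r = stats::cor(dat$performance, dat$act_diff),
       n = nrow(dat), data = dat)
}

#' Persistence of the decision signal across trials
#'
#' Decodes the choice made at a reference trial from hidden states at
#' every step from that trial onward (into the intertrial interval and
#' the following trials), mirroring the across-trial choice decoding in
#' recordings. With zeroed recurrence the choice cannot persist past the
#' decision trial.
#'
#' @param model A trained `rnn_model`.
#' @param run Optional precomputed [rnn_run()].
#' @param ref_trial Trial whose decision is decoded.
#' @param n_following How many subsequent trials to extend over.
#' @param folds,lambda,seed Decoder settings.
#' @return A `decoder_series` over the covered steps (labels: the decision
#'   at `ref_trial`).
#' @export
rnn_decision_persistence <- function(model, run = NULL, ref_trial = 3L,
                                     n_following = 2L, folds = 10L,
                                     lambda = 1e-3, seed = 1L) {
  if (is.null(run)) run <- rnn_run(model)
  tens <- rnn_tensor(run)
  clock <- task_clock()
  labels <- run$decision[, ref_trial]
  steps <- ((ref_trial - 1L) * clock$steps_per_trial + 1L):
    min((ref_trial + n_following) * clock$steps_per_trial, 75L)
  fit_timepoint_decoders(tens, labels, folds = folds, lambda = lambda,
                         timepoints = steps, seed = seed)
}
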