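#' Relevant-versus-irrelevant firing-rate contrast per neuron
#'
#' For each neuron, each modality and each stimulus sign (go/no-go),
#' compares the mean rate in the pre-reward window between trials where
#' that modality was relevant versus irrelevant. Significance uses
#' non-overlapping 2-s.e.m. bands around the two group means
#' (approximately the 0.05 level).
#'
#' @param tensor A `population_tensor` whose trial table has `visual`,
#'   `auditory`, `context`.
#' @param window Averaging window (s); default the 0.5 s before reward
#'   availability.
#' @param min_trials Minimum trials per group for a defined flag.
#' @return Data frame with columns `neuron`, `modality`, `signal`,
#'   `mean_relevant`, `mean_irrelevant`, `sem_relevant`, `sem_irrelevant`,
#'   `flag` (`"lower"`, `"higher"`, `"unmodulated"`, or `NA` when
#'   undefined).
#' @export
relevance_contrast <- function(tensor, window = c(1.5, 2), min_trials = 5L) {
  idx <- time_index(tensor, window)
  trials <- tensor$trials
  n_nr <- dim(tensor$rates)[2]
  mean_win <- apply(tensor$rates[, , idx, drop = FALSE], c(1, 2), mean)
  rows <- list()
  for (m in c("visual", "auditory")) {
    stim <- trials[[m]]
    for (sg in c(1L, 0L)) {
      rel <- trials$context == m & stim == sg
      irr <- trials$context != m & stim == sg
      for (j in seq_len(n_nr)) {
        if (sum(rel) < min_trials || sum(irr) < min_trials) {
          rows[[length(rows) + 1L]] <- data.frame(
            neuron = j, modality = m,
            signal = if (sg == 1L) "go" else "nogo",
            mean_relevant = NA_real_, mean_irrelevant = NA_real_,
            sem_relevant = NA_real_, sem_irrelevant = NA_real_,
            flag = NA_character_, stringsAsFactors = FALSE)
          next
        }
        xr <- mean_win[rel, j]; xi <- mean_win[irr, j]
        mr <- mean(xr); mi <- mean(xi)
        sr <- stats::sd(xr) / sqrt(length(xr))
        si <- stats::sd(xi) / sqrt(length(xi))
        flag <- if (mi + 2 * si < mr - 2 * sr) "lower"
        else if (mi - 2 * si > mr + 2 * sr) "higher"
        else "unmodulated"
        rows[[length(rows) + 1L]] <- data.frame(
          neuron = j, modality = m,
          signal = if (sg == 1L) "go" else "nogo",
          mean_relevant = mr, mean_irrelevant = mi,
          sem_relevant = sr, sem_irrelevant = si,
          flag = flag, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cross-validated variance explained by task variables
#'
#' Per neuron and timepoint, k-fold cross-validated linear regression of
#' the firing rate on one-hot binary task-variable predictors. Predictive
#' R-squared pools out-of-fold predictions: `1 - RSS/TSS`; negative values
#' mean the model predicts worse than the mean and are flagged as "no fit".
#'
#' @param tensor A `population_tensor`.
#' @param predictors Data frame (or named list) of per-trial binary
#'   predictors (e.g. stimulus identity, choice). Constant predictors are
#'   dropped with a message.
#' @param subset Optional trial subset.
#' @param folds CV folds.
#' @param seed Fold-assignment seed.
#' @return List with `r2` (neurons x timepoints, `NA` where no fit),
#'   `r2_raw` (signed values), `best_neuron`, `best_r2` (per timepoint),
#'   `predictors` used.
#' @export
variance_explained <- function(tensor, predictors, subset = NULL,
                               folds = 10L, seed = 1L) {
  P <- as.data.frame(predictors)
  keep <- seq_len(dim(tensor$rates)[1])
  if (!is.null(subset)) keep <- keep[subset]
  P <- P[keep, , drop = FALSE]
  const <- vapply(P, function(p) length(unique(p)) < 2L, logical(1))
  if (any(const)) {
    message("dropping constant predictor(s): ",
            paste(names(P)[const], collapse = ", "))
    P <- P[, !const, drop = FALSE]
  }
  if (ncol(P) == 0L) stop("no usable predictors", call. = FALSE)
  X <- cbind(1, as.matrix(P))
  n <- nrow(X)
  combo <- interaction(P, drop = TRUE)
  fold <- stratified_folds(as.integer(combo) %% 2L, folds, seed)
  n_nr <- dim(tensor$rates)[2]
  n_t <- length(tensor$time_s)
  r2 <- matrix(NA_real_, n_nr, n_t)
  for (k in seq_len(n_t)) {
    Y <- tensor$rates[keep, , k, drop = TRUE]
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = n_nr)
    pred <- matrix(NA_real_, n, n_nr)
    for (f in seq_len(folds)) {
      tr <- fold != f
      bet <- tryCatch(qr.solve(X[tr, , drop = FALSE], Y[tr, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(bet)) next
      pred[!tr, ] <- X[!tr, , drop = FALSE] %*% bet
    }
    rss <- colSums((Y - pred)^2)
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2[, k] <- 1 - rss / tss
  }
  r2_flagged <- r2
  r2_flagged[r2_flagged < 0] <- NA_real_
  best <- apply(r2_flagged, 2, function(col) {
    if (all(is.na(col))) NA_integer_ else which.max(col)
  })
  best_r2 <- vapply(seq_len(n_t), function(k) {
    if (is.na(best[k])) NA_real_ else r2_flagged[best[k], k]
  }, numeric(1))
  list(r2 = r2_flagged, r2_raw = r2, best_neuron = best,
       best_r2 = best_r2, predictors = names(P))
}

#' Compare explained variance of relevant versus irrelevant stimulus models
#'
#' Contrasts the best-neuron predictive R-squared of the two-predictor
#' models choice + relevant stimulus and choice + irrelevant stimulus,
#' block-averaged over the late-trial interval, with a one-tailed paired t
#' test (relevant > irrelevant).
#'
#' @param tensor A `population_tensor`.
#' @param choice,relevant,irrelevant Per-trial binary vectors.
#' @param subset Optional trial subset.
#' @param range,width Block-averaging interval and width (s).
#' @param folds,seed As in [variance_explained()].
#' @return List with `blocks_relevant`, `blocks_irrelevant`, `t`, `p`,
#'   `excess` (mean block difference), and the two [variance_explained()]
#'   results.
#' @export
compare_variance_models <- function(tensor, choice, relevant, irrelevant,
                                    subset = NULL, range = c(0.6, 3),
                                    width = 0.6, folds = 10L, seed = 1L) {
  ve_rel <- variance_explained(
    tensor, data.frame(choice = choice, stimulus = relevant),
    subset = subset, folds = folds, seed = seed)
  ve_irr <- variance_explained(
    tensor, data.frame(choice = choice, stimulus = irrelevant),
    subset = subset, folds = folds, seed = seed)
  miss <- is.na(ve_rel$best_r2) | is.na(ve_irr$best_r2)
  vr <- ve_rel$best_r2; vi <- ve_irr$best_r2
  vr[miss] <- NA; vi[miss] <- NA
  br <- block_average(ifelse(is.na(vr), 0, vr), tensor$time_s,
                      width = width, range = range)
  bi <- block_average(ifelse(is.na(vi), 0, vi), tensor$time_s,
                      width = width, range = range)
  d <- br$block_mean - bi$block_mean
  if (stats::sd(d) == 0) {
    # degenerate: identical block means in every window
    tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
               p.value = if (mean(d) > 0) 0 else 1)
  } else {
    tt <- stats::t.test(br$block_mean, bi$block_mean, paired = TRUE,
                        alternative = "greater")
  }
  list(blocks_relevant = br$block_mean, blocks_irrelevant = bi$block_mean,
       t = unname(tt$statistic), p = tt$p.value,
       excess = mean(br$block_mean - bi$block_mean),
       ve_relevant = ve_rel, ve_irrelevant = ve_irr)
}

#' Per-neuron modality index from decoder coefficients
#'
#' Signed difference between each neuron's visual and auditory decoder
#' coefficients (or input weights): positive for visually driven neurons,
#' negative for auditory, near zero for mixed or weakly driven cells.
#'
#' @param dv_visual,dv_auditory Coefficient vectors of the two stimulus
#'   decoders over the same neurons.
#' @return Numeric vector of per-neuron indices.
#' @export
modality_index <- function(dv_visual, dv_auditory) {
  stopifnot(length(dv_visual) == length(dv_auditory))
  as.numeric(dv_visual) - as.numeric(dv_auditory)
}

#' Per-neuron context index from congruent-trial activity
#'
#' Mean activity difference between the visual and the auditory context,
#' averaged over trials and window timepoints. Only congruent trials enter
#' so the index is not trivially driven by the go/no-go reversal of the
#' relevant signal on incongruent trials. Window presets follow the trial
#' stages: `"trial"` (whole trial), `"pre"` (-1.0 to -0.25 s), `"start"`
#' (0 to 0.75 s), `"dec"` (1.75 to 2.5 s).
#'
#' @param tensor A `population_tensor`.
#' @param window Preset name or numeric `c(start, end)` in seconds.
#' @param signal Optionally restrict to `"go"` or `"nogo"` congruent
#'   trials (for signal-wise indices); default uses all congruent trials.
#' @return Numeric vector of per-neuron indices.
#' @export
context_index <- function(tensor, window = "trial", signal = NULL) {
  if (is.character(window)) {
    window <- switch(match.arg(window, c("trial", "pre", "start", "dec")),
                     trial = c(min(tensor$time_s), max(tensor$time_s) + 1e-9),
                     pre = c(-1, -0.25), start = c(0, 0.75),
                     dec = c(1.75, 2.5))
  }
  idx <- time_index(tensor, window)
  trials <- tensor$trials
  con <- trials$visual == trials$auditory
  if (!is.null(signal)) {
    sg <- if (match.arg(signal, c("go", "nogo")) == "go") 1L else 0L
    con <- con & trials$visual == sg
  }
  iv <- which(con & trials$context == "visual")
  ia <- which(con & trials$context == "auditory")
  if (length(iv) == 0L || length(ia) == 0L) {
    stop("both contexts need congruent trials in the window", call. = FALSE)
  }
  mv <- apply(tensor$rates[iv, , idx, drop = FALSE], 2, mean)
  ma <- apply(tensor$rates[ia, , idx, drop = FALSE], 2, mean)
  mv - ma
}

#' Correlation between context index and modality rank
#'
#' Pearson correlation of per-neuron context indices against the neurons'
#' modality rank (descending modality index). Mutual suppression between
#' modality-specific populations predicts a negative correlation: neurons
#' preferring a modality are more active in the context where that
#' modality is relevant.
#'
#' @param modality_idx Per-neuron modality index (used for ranking), or an
#'   already-computed rank when `is_rank = TRUE`.
#' @param context_idx Per-neuron context index.
#' @param use_rank Correlate against rank (default) or raw index.
#' @param trim Number of extreme rank positions to drop at each end
#'   (display parity; 0 keeps all neurons).
#' @param is_rank `modality_idx` is already a rank vector.
#' @return List with `r`, `t`, `p`, `n`, `df`.
#' @export
modality_context_correlation <- function(modality_idx, context_idx,
                                         use_rank = TRUE, trim = 0L,
                                         is_rank = FALSE) {
  ok <- !is.na(modality_idx) & !is.na(context_idx)
  mi <- modality_idx[ok]; ci <- context_idx[ok]
  if (length(mi) < 3L) stop("need at least 3 neurons", call. = FALSE)
  rk <- if (is_rank) mi else rank(-mi, ties.method = "first")
  if (trim > 0L) {
    keep <- rk > trim & rk <= (length(rk) - trim)
    rk <- rk[keep]; ci <- ci[keep]; mi <- mi[keep]
  }
  x <- if (use_rank) rk else mi
  if (stats::sd(x) == 0 || stats::sd(ci) == 0) {
    return(list(r = NA_real_, t = NA_real_, p = NA_real_,
                n = length(x), df = length(x) - 2L, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, ci)
  list(r = unname(ct$estimate), t = unname(ct$statistic), p = ct$p.value,
       n = length(x), df = unname(ct$parameter), degenerate = FALSE)
}
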