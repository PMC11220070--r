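#' Bernoulli choice models for go/no-go licking
#'
#' Constructs a per-trial lick-probability model. Families:
#' \describe{
#'   \item{`correct_modality`}{licks iff the contextually relevant modality
#'     shows "go" (P = 1 for go, 0 for no-go, before clipping).}
#'   \item{`opposite_modality`}{follows the irrelevant modality instead.}
#'   \item{`random_bias`}{context-agnostic constant lick probability
#'     `p_lick` (typically the empirical lick rate).}
#'   \item{`context_aware_bias`}{P = 1 + beta for relevant go, beta for
#'     relevant no-go, clipped after adding the bias.}
#'   \item{`context_aware_lapse`}{P = 1 - lambda for relevant go, lambda
#'     for relevant no-go.}
#' }
#' All probabilities are clipped to \[0.001, 0.999\].
#'
#' @param family One of the model family names above.
#' @param beta Additive lick bias in \[0, 1\] (`context_aware_bias`).
#' @param lambda Lapse rate in \[0, 1\] (`context_aware_lapse`).
#' @param p_lick Constant lick probability (`random_bias`).
#' @return An object of class `choice_model`.
#' @export
choice_model <- function(family = c("correct_modality", "opposite_modality",
                                    "random_bias", "context_aware_bias",
                                    "context_aware_lapse"),
                         beta = 0, lambda = 0, p_lick = 0.5) {
  family <- match.arg(family)
  stopifnot(beta >= 0, beta <= 1, lambda >= 0, lambda <= 1,
            p_lick >= 0, p_lick <= 1)
  structure(list(family = family, beta = beta, lambda = lambda,
                 p_lick = p_lick), class = "choice_model")
}

.clip_p <- function(p, lo = 0.001, hi = 0.999) pmin(pmax(p, lo), hi)

#' Per-trial lick probability under a choice model
#'
#' @param model A [choice_model()].
#' @param trials Data frame with columns `visual`, `auditory`, `context`.
#' @return Numeric vector of clipped lick probabilities.
#' @export
lick_probability <- function(model, trials) {
  stopifnot(inherits(model, "choice_model"))
  go <- contextual_target(trials$visual, trials$auditory, trials$context)
  anti <- contextual_target(trials$visual, trials$auditory,
                            ifelse(trials$context == "visual",
                                   "auditory", "visual"))
  p <- switch(model$family,
    correct_modality = as.numeric(go),
    opposite_modality = as.numeric(anti),
    random_bias = rep(model$p_lick, length(go)),
    context_aware_bias = ifelse(go == 1, 1 + model$beta, model$beta),
    context_aware_lapse = ifelse(go == 1, 1 - model$lambda, model$lambda)
  )
  .clip_p(p)
}

#' Mean log-likelihood of observed choices under a model
#'
#' Used to compare choice strategies on the consistent incongruent trials,
#' where context-aware and context-unaware strategies differ.
#'
#' @param model A [choice_model()].
#' @param trials Data frame with `visual`, `auditory`, `context`, `lick`.
#' @return Mean over trials of log P(observed lick).
#' @export
choice_model_loglik <- function(model, trials) {
  if (nrow(trials) == 0L) {
    stop("`trials` is empty: mean log-likelihood undefined", call. = FALSE)
  }
  p <- lick_probability(model, trials)
  mean(ifelse(trials$lick == 1, log(p), log(1 - p)))
}

#' Behavioral sensitivity d'
#'
#' Difference of inverse-normal-transformed hit and false-alarm rates, with
#' rates clipped to \[0.01, 0.99\] so extreme sessions stay finite.
#'
#' @param hits Hit rate in \[0, 1\].
#' @param false_alarms False-alarm rate in \[0, 1\].
#' @return d' value (vectorized).
#' @export
d_prime <- function(hits, false_alarms) {
  stopifnot(all(hits >= 0 & hits <= 1), all(false_alarms >= 0 &
                                              false_alarms <= 1))
  clip <- function(r) pmin(pmax(r, 0.01), 0.99)
  stats::qnorm(clip(hits)) - stats::qnorm(clip(false_alarms))
}

#' Simulate a context-switching behavioural session
#'
#' Draws per-trial stimuli uniformly and licks from the given choice model,
#' over blocks of constant context. Trial timing follows the 3-s trial with
#' reward available during the final second.
#'
#' @param model A [choice_model()].
#' @param blocks Data frame with columns `context` and `n_trials`, one row
#'   per context block.
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return A data frame of class `behavior_session` with columns
#'   `trial_index`, `block`, `context`, `visual`, `auditory`, `congruent`,
#'   `target`, `lick`, `correct`, `t_stim_on_s`, `t_reward_s`.
#' @export
simulate_behavior <- function(model, blocks, seed = 1L) {
  stopifnot(inherits(model, "choice_model"),
            all(c("context", "n_trials") %in% names(blocks)))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(blocks)), function(b) {
    n <- blocks$n_trials[b]
    data.frame(block = b, context = blocks$context[b],
               visual = sample(0:1, n, replace = TRUE),
               auditory = sample(0:1, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ses <- do.call(rbind, rows)
  ses$trial_index <- seq_len(nrow(ses))
  ses$congruent <- classify_congruence(ses$visual, ses$auditory)
  ses$target <- contextual_target(ses$visual, ses$auditory, ses$context)
  p <- lick_probability(model, ses)
  ses$lick <- as.integer(stats::runif(nrow(ses)) < p)
  ses$correct <- as.integer(ses$lick == ses$target)
  ses$t_stim_on_s <- (ses$trial_index - 1L) * 6
  ses$t_reward_s <- ses$t_stim_on_s + 2
  ses <- ses[, c("trial_index", "block", "context", "visual", "auditory",
                 "congruent", "target", "lick", "correct", "t_stim_on_s",
                 "t_reward_s")]
  class(ses) <- c("behavior_session", "data.frame")
  ses
}

# Shrinking-window moving average: mean over positions within +/- hw,
# truncated at the ends so a value is defined at every position.
.moving_mean <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  hw <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - hw, 1L)
  hi <- pmin(i + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# carry values defined at positions `pos` (sorted) to every trial 1..n:
# each trial takes the value at the nearest preceding position, or the
# first position for trials before it; returns index into `pos` per trial
.carry_index <- function(pos, n) {
  if (length(pos) == 0L) return(rep(NA_integer_, n))
  idx <- findInterval(seq_len(n), pos)
  idx[idx == 0L] <- 1L
  idx
}

#' Moving-average performance curves and consistency segmentation
#'
#' Within each context block, computes equal-weight moving averages of
#' fraction-correct separately for the four trial types (go/no-go crossed
#' with congruent/incongruent). Windows shrink at block edges so every
#' trial has a defined value; between trials of a type the curve is carried
#' from the nearest preceding trial of that type. A trial is
#' "task-consistent" when all four curves are at (or above) chance 0.5;
#' with `strict = TRUE` the comparison is strictly above.
#'
#' @param session A `behavior_session` data frame (needs `block`, `target`,
#'   `congruent`, `correct`).
#' @param window Odd moving-average window in trials of the same type.
#' @param strict Use `>` chance rather than `>=`.
#' @return List with `curves` (data frame: per-trial values of the four
#'   curves, `NA` where the type is absent from the block), and
#'   `consistent` (logical per trial).
#' @export
moving_average_performance <- function(session, window = 21L,
                                       strict = FALSE) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- nrow(session)
  type_go <- session$target == 1L
  type_con <- session$congruent
  curves <- matrix(NA_real_, n, 4L)
  colnames(curves) <- c("go_congruent", "go_incongruent",
                        "nogo_congruent", "nogo_incongruent")
  consistent <- rep(FALSE, n)
  cmp <- if (strict) `>` else `>=`
  for (b in unique(session$block)) {
    in_b <- which(session$block == b)
    ok <- rep(TRUE, length(in_b))
    for (k in 1:4) {
      go <- k <= 2L
      con <- k %% 2L == 1L
      pos <- which(type_go[in_b] == go & type_con[in_b] == con)
      if (length(pos) == 0L) { ok[] <- FALSE; next }
      mm <- .moving_mean(session$correct[in_b][pos], window)
      idx <- .carry_index(pos, length(in_b))
      curves[in_b, k] <- mm[idx]
      ok <- ok & cmp(mm[idx], 0.5)
    }
    consistent[in_b] <- ok
  }
  list(curves = as.data.frame(curves), consistent = consistent)
}

# Consistent-trial count for many simulated incongruent-outcome vectors at
# once. Congruent trials are forced correct. `inc_correct` is an
# (n incongruent x n sims) 0/1 matrix in block trial order.
.null_consistent_counts <- function(block, inc_correct, window, strict) {
  n <- nrow(block)
  type_go <- block$target == 1L
  inc <- !block$congruent
  cmp <- if (strict) `>` else `>=`
  # congruent curves: all-correct -> pass wherever the type exists;
  # a missing congruent type fails the whole block mask
  con_ok <- TRUE
  for (go in c(TRUE, FALSE)) {
    if (!any(type_go == go & !inc)) con_ok <- FALSE
  }
  if (!con_ok) return(rep(0L, ncol(inc_correct)))
  counts <- rep(0L, ncol(inc_correct))
  pass <- matrix(TRUE, n, ncol(inc_correct))
  for (go in c(TRUE, FALSE)) {
    pos_in_inc <- which(type_go[inc] == go)      # rows of inc_correct
    pos_in_block <- which(type_go == go & inc)   # block trial positions
    if (length(pos_in_block) == 0L) return(rep(0L, ncol(inc_correct)))
    hw <- (window - 1L) %/% 2L
    m <- length(pos_in_block)
    cs <- rbind(0, apply(inc_correct[pos_in_inc, , drop = FALSE], 2, cumsum))
    i <- seq_len(m)
    lo <- pmax(i - hw, 1L); hi <- pmin(i + hw, m)
    mm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
    idx <- .carry_index(pos_in_block, n)
    pass <- pass & cmp(mm[idx, , drop = FALSE], 0.5)
  }
  colSums(pass)
}

#' Monte-Carlo null probability of the observed consistency
#'
#' Tests whether the observed number of task-consistent trials in a context
#' block could arise from a context-unaware strategy: simulated sessions
#' keep the block's trial sequence, force congruent trials correct, and draw
#' incongruent licks from a Bernoulli distribution at the block's empirical
#' incongruent lick rate. Returns the probability of observing at least the
#' empirical number of consistent trials.
#'
#' @param session A `behavior_session` data frame.
#' @param n_sim Number of simulated sessions (default 1e6).
#' @param seed Integer seed for the simulation draws.
#' @param window,strict Passed to [moving_average_performance()].
#' @param chunk Sessions simulated per vectorized chunk.
#' @return Data frame, one row per context block: `block`, `context`,
#'   `n_trials`, `n_incongruent`, `lick_rate_incongruent`,
#'   `observed_consistent`, `p_null`, `log10_p`.
#' @export
consistency_null_probability <- function(session, n_sim = 1e6, seed = 1L,
                                         window = 21L, strict = FALSE,
                                         chunk = 20000L) {
  obs <- moving_average_performance(session, window, strict)
  set.seed(seed)
  out <- lapply(unique(session$block), function(b) {
    blk <- session[session$block == b, ]
    inc <- !blk$congruent
    if (!any(inc)) {
      stop(sprintf("block %s has no incongruent trials: null undefined", b),
           call. = FALSE)
    }
    p_lick <- mean(blk$lick[inc])
    n_inc <- sum(inc)
    # correctness probability per incongruent trial: go target -> lick
    # correct (prob p_lick); no-go target -> withhold correct (1 - p_lick)
    p_correct <- ifelse(blk$target[inc] == 1L, p_lick, 1 - p_lick)
    observed <- sum(obs$consistent[session$block == b])
    done <- 0L
    n_ge <- 0
    while (done < n_sim) {
      m <- min(chunk, n_sim - done)
      draws <- matrix(stats::runif(n_inc * m) < p_correct, n_inc, m)
      cnt <- .null_consistent_counts(blk, draws + 0L, window, strict)
      n_ge <- n_ge + sum(cnt >= observed)
      done <- done + m
    }
    p <- n_ge / n_sim
    data.frame(block = b, context = blk$context[1L], n_trials = nrow(blk),
               n_incongruent = n_inc, lick_rate_incongruent = p_lick,
               observed_consistent = observed, p_null = p,
               log10_p = log10(max(p, 1 / n_sim)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact enumeration version of the consistency null
#'
#' Enumerates all 2^k incongruent outcome vectors of a block (feasible for
#' small k) and sums the exact probabilities of outcomes with at least the
#' observed number of consistent trials. Serves as the ground-truth check
#' for [consistency_null_probability()].
#'
#' @inheritParams consistency_null_probability
#' @param max_incongruent Guard on enumeration size.
#' @return Data frame as [consistency_null_probability()] (without
#'   Monte-Carlo error).
#' @export
consistency_null_exact <- function(session, window = 21L, strict = FALSE,
                                   max_incongruent = 16L) {
  obs <- moving_average_performance(session, window, strict)
  out <- lapply(unique(session$block), function(b) {
    blk <- session[session$block == b, ]
    inc <- !blk$congruent
    if (!any(inc)) {
      stop(sprintf("block %s has no incongruent trials: null undefined", b),
           call. = FALSE)
    }
    n_inc <- sum(inc)
    if (n_inc > max_incongruent) {
      stop("too many incongruent trials for exact enumeration",
           call. = FALSE)
    }
    p_lick <- mean(blk$lick[inc])
    p_correct <- ifelse(blk$target[inc] == 1L, p_lick, 1 - p_lick)
    grid <- as.matrix(expand.grid(rep(list(0:1), n_inc)))
    probs <- apply(grid, 1, function(g) {
      prod(ifelse(g == 1, p_correct, 1 - p_correct))
    })
    cnt <- .null_consistent_counts(blk, t(grid), window, strict)
    observed <- sum(obs$consistent[session$block == b])
    p <- sum(probs[cnt >= observed])
    data.frame(block = b, context = blk$context[1L], n_trials = nrow(blk),
               n_incongruent = n_inc, lick_rate_incongruent = p_lick,
               observed_consistent = observed, p_null = p,
               log10_p = log10(max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the lapse parameter of the context-aware model by maximum likelihood
#'
#' One-dimensional likelihood maximization of the `context_aware_lapse`
#' family on a set of trials; used for parameter-recovery checks.
#'
#' @param trials Data frame with `visual`, `auditory`, `context`, `lick`.
#' @return List with `lambda` and `loglik` (mean log-likelihood).
#' @export
fit_lapse <- function(trials) {
  f <- function(l) {
    -choice_model_loglik(choice_model("context_aware_lapse", lambda = l),
                         trials)
  }
  opt <- stats::optimize(f, c(0, 1))
  list(lambda = opt$minimum, loglik = -opt$objective)
}
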