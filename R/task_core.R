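#' Task clock constants for the sequence-level network model
#'
#' The within-trial clock used by the recurrent network: 15 timesteps per
#' trial, a 9-step stimulus presentation flanked by 3 pre- and 3
#' post-stimulus steps, and the decision read out at the 7th stimulus step
#' (trial step 10).
#'
#' @return A list with elements `steps_per_trial`, `stim_on`, `stim_off`,
#'   `decision_step` (all 1-indexed trial steps) and `trials_per_sequence`.
#' @export
task_clock <- function() {
  list(steps_per_trial = 15L, stim_on = 4L, stim_off = 12L,
       decision_step = 10L, trials_per_sequence = 5L)
}

.check_binary <- function(x, name) {
  if (!all(x %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be binary (0 = no-go, 1 = go)", name),
         call. = FALSE)
  }
}

.check_context <- function(context) {
  context <- match.arg(context, c("visual", "auditory"))
  context
}

#' Classify trial congruence
#'
#' A trial is congruent when both modalities instruct the same response, so
#' the trial carries no information about which modality is relevant.
#'
#' @param visual,auditory Binary stimulus codes (1 = go, 0 = no-go);
#'   vectors are recycled by the usual rules.
#' @return Logical vector: `TRUE` for congruent trials.
#' @export
classify_congruence <- function(visual, auditory) {
  .check_binary(visual, "visual")
  .check_binary(auditory, "auditory")
  visual == auditory
}

#' Contextual target response
#'
#' @param visual,auditory Binary stimulus codes (1 = go).
#' @param context `"visual"` or `"auditory"`; may be a vector.
#' @return Binary target (1 = lick/go) under the given context.
#' @export
contextual_target <- function(visual, auditory, context) {
  .check_binary(visual, "visual")
  .check_binary(auditory, "auditory")
  if (!all(context %in% c("visual", "auditory"))) {
    stop("`context` must be \"visual\" or \"auditory\"", call. = FALSE)
  }
  n <- max(length(visual), length(auditory), length(context))
  visual <- rep_len(visual, n)
  auditory <- rep_len(auditory, n)
  context <- rep_len(context, n)
  ifelse(context == "visual", visual, auditory)
}

#' Enumerate all five-trial sequences for one context
#'
#' Builds the exhaustive combinatorial space of 4^5 = 1024 stimulus
#' sequences (2 visual x 2 auditory stimuli per trial, 5 trials) sharing one
#' context. Ordering is lexicographic in the trial-wise (visual, auditory)
#' codes with trial 1 most significant, so the enumeration is reproducible
#' without a seed. A sequence is unsolvable when its first four trials are
#' all congruent (carrying no context information) and the final trial is
#' incongruent.
#'
#' @param context `"visual"` or `"auditory"`.
#' @return A data frame with one row per trial (`1024 * 5` rows) and columns
#'   `context`, `sequence_id` (1-based within context), `trial_index` (1-5),
#'   `visual`, `auditory`, `target`, `congruent`, `solvable`.
#' @export
enumerate_sequences <- function(context = c("visual", "auditory")) {
  context <- .check_context(context)
  n_trials <- 5L
  codes <- as.matrix(expand.grid(rep(list(0:3), n_trials))[, n_trials:1])
  # column t = code of trial t; code s = 2 * visual + auditory
  colnames(codes) <- NULL
  n_seq <- nrow(codes)                      # 4^5
  seq_id <- rep(seq_len(n_seq), each = n_trials)
  trial_index <- rep(seq_len(n_trials), times = n_seq)
  s <- as.integer(t(codes))                 # row-major: trial fast
  visual <- s %/% 2L
  auditory <- s %% 2L
  congruent <- visual == auditory
  target <- if (context == "visual") visual else auditory
  cong_mat <- matrix(congruent, nrow = n_trials)
  solvable_seq <- !(colSums(cong_mat[1:4, , drop = FALSE]) == 4L &
                      !cong_mat[5L, ])
  data.frame(
    context = context,
    sequence_id = seq_id,
    trial_index = trial_index,
    visual = visual,
    auditory = auditory,
    target = as.integer(target),
    congruent = congruent,
    solvable = solvable_seq[seq_id],
    stringsAsFactors = FALSE
  )
}

#' Build the full training dataset of five-trial sequences
#'
#' Union of both contexts' exhaustive enumerations: 2048 unique sequences.
#' The whole dataset is used for training the network; there is no held-out
#' split because every sequence is unique, every solvable sequence is
#' deterministically solvable, and there is no stochasticity in the data.
#'
#' @return A data frame as [enumerate_sequences()], with both contexts
#'   stacked; class `c("sequence_dataset", "data.frame")`.
#' @export
build_dataset <- function() {
  out <- rbind(enumerate_sequences("visual"), enumerate_sequences("auditory"))
  class(out) <- c("sequence_dataset", "data.frame")
  out
}

#' Stimulus-code matrix view of a sequence dataset
#'
#' Compact encoding used by the network rollout: one row per sequence with
#' per-trial codes `s = 2 * visual + auditory` in 0..3.
#'
#' @param dataset A data frame from [build_dataset()] or
#'   [enumerate_sequences()].
#' @return A list with `stim` (integer matrix, sequences x 5), `context`
#'   (integer, 0 = visual, 1 = auditory), `solvable`, and
#'   `final_congruent` (logical, congruence of trial 5).
#' @export
sequence_codes <- function(dataset) {
  key <- paste(dataset$context, dataset$sequence_id)
  ord <- order(match(key, unique(key)), dataset$trial_index)
  d <- dataset[ord, ]
  n_seq <- nrow(d) %/% 5L
  s <- matrix(2L * d$visual + d$auditory, nrow = n_seq, ncol = 5L,
              byrow = TRUE)
  first <- d[d$trial_index == 1L, ]
  list(stim = s,
       context = as.integer(first$context == "auditory"),
       solvable = first$solvable,
       final_congruent = d$congruent[d$trial_index == 5L])
}

#' Ideal-observer solvability of a sequence
#'
#' Brute-force check used as an oracle for the `solvable` flag: the context
#' is identifiable from the stimulus-target contingencies of trials 1-4 iff
#' at least one of them is incongruent; only then can the final trial of an
#' incongruent type be answered above chance.
#'
#' @param visual,auditory Length-5 binary vectors for one sequence.
#' @return `TRUE` if an ideal observer can guarantee a correct final-trial
#'   decision in both contexts' versions of the sequence.
#' @export
ideal_observer_solvable <- function(visual, auditory) {
  stopifnot(length(visual) == 5L, length(auditory) == 5L)
  congruent <- classify_congruence(visual, auditory)
  if (congruent[5L]) return(TRUE)
  any(!congruent[1:4])
}
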