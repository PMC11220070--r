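test_that("congruence classification covers the stimulus combinations", {
  expect_true(classify_congruence(1L, 1L))
  expect_true(classify_congruence(0L, 0L))
  expect_false(classify_congruence(1L, 0L))
  expect_false(classify_congruence(0L, 1L))
  grid <- expand.grid(v = 0:1, a = 0:1)
  expect_identical(sum(classify_congruence(grid$v, grid$a)), 2L)
  expect_error(classify_congruence(2L, 0L), "binary")
})

test_that("contextual target follows the relevant modality", {
  expect_identical(contextual_target(1L, 0L, "visual"), 1L)
  expect_identical(contextual_target(1L, 0L, "auditory"), 0L)
  # incongruent targets flip with context, congruent targets do not
  grid <- expand.grid(v = 0:1, a = 0:1)
  tv <- contextual_target(grid$v, grid$a, "visual")
  ta <- contextual_target(grid$v, grid$a, "auditory")
  con <- classify_congruence(grid$v, grid$a)
  expect_true(all((tv == ta) == con))
})

test_that("sequence enumeration is exhaustive, unique and correctly flagged", {
  for (ctx in c("visual", "auditory")) {
    seqs <- enumerate_sequences(ctx)
    expect_identical(nrow(seqs), 1024L * 5L)
    key <- tapply(paste(seqs$visual, seqs$auditory), seqs$sequence_id,
                  paste, collapse = "|")
    expect_identical(length(unique(key)), 1024L)
    first <- seqs[seqs$trial_index == 1L, ]
    expect_identical(sum(!first$solvable), 32L)
    all_con <- tapply(seqs$congruent, seqs$sequence_id, all)
    expect_identical(sum(all_con), 32L)
  }
})

test_that("solvable flag matches the ideal-observer oracle everywhere", {
  seqs <- enumerate_sequences("auditory")
  agree <- vapply(seq_len(1024L), function(id) {
    rows <- seqs[seqs$sequence_id == id, ]
    ideal_observer_solvable(rows$visual, rows$auditory) ==
      rows$solvable[1L]
  }, logical(1))
  expect_true(all(agree))
})

test_that("full dataset has 2048 unique sequences, 3.125% unsolvable", {
  ds <- build_dataset()
  first <- ds[ds$trial_index == 1L, ]
  expect_identical(nrow(first), 2048L)
  expect_equal(mean(!first$solvable), 64 / 2048)
  codes <- sequence_codes(ds)
  expect_identical(dim(codes$stim), c(2048L, 5L))
  expect_identical(anyDuplicated(cbind(codes$context, codes$stim)), 0L)
  # code round trip matches the table encoding
  expect_identical(codes$stim[, 1L] %/% 2L,
                   first$visual)
})

test_that("the task clock matches the trial structure", {
  clock <- task_clock()
  expect_identical(clock$steps_per_trial, 15L)
  expect_identical(clock$stim_off - clock$stim_on + 1L, 9L)
  expect_identical(clock$stim_on - 1L, 3L)
  expect_identical(clock$decision_step, clock$stim_on + 6L)
})
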