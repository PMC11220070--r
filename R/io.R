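#' Read and validate a trial table
#'
#' @param path CSV file with at least `trial_index`, `context`, `visual`,
#'   `auditory`; additional columns (`congruent`, `lick`, `correct`,
#'   timing) are kept.
#' @return Validated data frame with normalized context labels and a
#'   recomputed `congruent` column.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_index", "context", "visual", "auditory")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$context <- tolower(trimws(tab$context))
  bad_ctx <- which(!tab$context %in% c("visual", "auditory"))
  if (length(bad_ctx) > 0L) {
    stop(sprintf("invalid context label in row %d: %s", bad_ctx[1L],
                 tab$context[bad_ctx[1L]]), call. = FALSE)
  }
  for (col in c("visual", "auditory")) {
    bad <- which(!tab[[col]] %in% c(0L, 1L))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary `%s` code in row %d", col, bad[1L]),
           call. = FALSE)
    }
  }
  tab$congruent <- tab$visual == tab$auditory
  tab
}

#' Write a trial table
#'
#' @param trials Data frame.
#' @param path Output CSV path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write a sequence dataset to CSV
#'
#' @param dataset From [build_dataset()] or [enumerate_sequences()].
#' @param path Output CSV path.
#' @export
write_sequences <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a population container
#'
#' A container bundles the firing-rate tensor, its time axis, the trial
#' table and standardization metadata in one file, the unit every analysis
#' stage reads. Containers are serialized R objects (`.rds`); reading
#' validates the layout and shape consistency.
#'
#' @param tensor A `population_tensor`.
#' @param path File path (`.rds`).
#' @return `write_container` the path; `read_container` the validated
#'   `population_tensor`.
#' @export
write_container <- function(tensor, path) {
  stopifnot(inherits(tensor, "population_tensor"))
  saveRDS(tensor, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$rates) || is.null(obj$trials)) {
    stop("not a population container: missing rates or trial table",
         call. = FALSE)
  }
  if (is.null(obj$time_s)) {
    stop("not a population container: missing time axis", call. = FALSE)
  }
  if (dim(obj$rates)[1] != nrow(obj$trials)) {
    stop(sprintf(
      "container shape mismatch: %d tensor trials vs %d table rows",
      dim(obj$rates)[1], nrow(obj$trials)), call. = FALSE)
  }
  population_tensor(obj$rates, obj$time_s, obj$trials, obj$meta)
}

#' Default pipeline configuration
#'
#' One declarative list holding every stage's parameters; all randomness
#' derives from `seed`. `run_pipeline()` accepts this list (or a YAML file
#' with the same fields) so a full synthetic-data analysis is reproducible
#' from the config alone.
#'
#' @param seed Master seed.
#' @return Named list of stage parameter blocks.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    behavior = list(
      lapse = 0.1,
      blocks = data.frame(context = c("visual", "auditory"),
                          n_trials = c(120L, 120L)),
      window = 21L,
      n_sim = 10000L
    ),
    population = list(
      n_neurons = 60L, dt = 0.1, noise_sd = 2,
      suppression_gamma = 0.2, preset = "mixed", angle_va = 90
    ),
    decoding = list(folds = 10L, lambda = 1e-3, min_per_class = 10L),
    indices = list(window = "trial"),
    rnn = list(enabled = FALSE, n_models = 3L, epochs = 5000L,
               lr = 1e-4, batch_size = 8L, min_performance = 0.9)
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    raw <- yaml::read_yaml(config)
    base <- default_config(if (is.null(raw$seed)) 1L else raw$seed)
    for (nm in names(raw)) {
      if (is.list(raw[[nm]]) && is.list(base[[nm]])) {
        for (k in names(raw[[nm]])) base[[nm]][[k]] <- raw[[nm]][[k]]
      } else {
        base[[nm]] <- raw[[nm]]
      }
    }
    if (!is.null(raw$behavior$blocks)) {
      base$behavior$blocks <- as.data.frame(raw$behavior$blocks)
    }
    base
  } else {
    config
  }
}

#' Run the synthetic-data analysis pipeline
#'
#' Executes simulate - generate - standardize - decode - indices (and
#' optionally network training and analysis) and writes each stage's
#' summary tables plus a manifest to `out_dir`. Outputs are deterministic
#' functions of the configuration.
#'
#' @param config A config list from [default_config()] (possibly
#'   modified) or the path of a YAML file with the same fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame of written files.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  cfg <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }

  # behavioural stage
  model <- choice_model("context_aware_lapse", lambda = cfg$behavior$lapse)
  session <- simulate_behavior(model, cfg$behavior$blocks,
                               seed = cfg$seed)
  emit(session, "session.csv")
  mam <- moving_average_performance(session, cfg$behavior$window)
  emit(cbind(trial_index = session$trial_index, mam$curves,
             consistent = mam$consistent), "consistency.csv")
  null_tab <- consistency_null_probability(
    session, n_sim = cfg$behavior$n_sim, seed = cfg$seed + 1L,
    window = cfg$behavior$window)
  emit(null_tab, "consistency_null.csv")

  # synthetic population + preprocessing
  spec <- population_spec(
    n_neurons = cfg$population$n_neurons, dt = cfg$population$dt,
    noise_sd = cfg$population$noise_sd,
    suppression_gamma = cfg$population$suppression_gamma,
    preset = cfg$population$preset, angle_va = cfg$population$angle_va,
    embed_seed = cfg$seed)
  tensor <- generate_population(spec, session, seed = cfg$seed + 2L)
  tensor <- zscore_baseline(tensor)
  write_container(tensor, file.path(out_dir, "population.rds"))
  written <- c(written, file.path(out_dir, "population.rds"))

  # decoding stage: stimulus decoders in each context + suppression
  dec <- cfg$decoding
  sup_rows <- list()
  for (m in c("visual", "auditory")) {
    rel <- fit_timepoint_decoders(
      tensor, tensor$trials[[m]], subset = session$context == m,
      folds = dec$folds, min_per_class = dec$min_per_class,
      lambda = dec$lambda, seed = cfg$seed)
    irr <- fit_timepoint_decoders(
      tensor, tensor$trials[[m]], subset = session$context != m,
      folds = dec$folds, min_per_class = dec$min_per_class,
      lambda = dec$lambda, seed = cfg$seed)
    sp <- suppression_metric(rel, irr)
    if (sp$available) {
      sup_rows[[m]] <- data.frame(
        modality = m, block_start = sp$block_start,
        block_difference = sp$block_difference, t = sp$t, p = sp$p,
        stringsAsFactors = FALSE)
    }
  }
  emit(do.call(rbind, sup_rows), "suppression.csv")

  # geometry: DV angles in the early-stimulus window
  early <- time_index(tensor, c(0.25, 0.75))
  dvs <- lapply(c(visual = "visual", auditory = "auditory"), function(m) {
    ds <- fit_timepoint_decoders(tensor, tensor$trials[[m]],
                                 folds = dec$folds, lambda = dec$lambda,
                                 timepoints = early, seed = cfg$seed)
    rowMeans(ds$dv)
  })
  ctx_ds <- fit_timepoint_decoders(
    tensor, as.integer(tensor$trials$context == "visual"),
    folds = dec$folds, lambda = dec$lambda, timepoints = early,
    seed = cfg$seed)
  dv_ctx <- rowMeans(ctx_ds$dv)
  emit(data.frame(
    pair = c("visual_auditory", "context_visual", "context_auditory"),
    angle_deg = c(dv_angle(dvs$visual, dvs$auditory),
                  dv_angle(dv_ctx, dvs$visual),
                  dv_angle(dv_ctx, dvs$auditory))), "angles.csv")

  # single-neuron indices
  midx <- modality_index(dvs$visual, dvs$auditory)
  cidx <- context_index(tensor, cfg$indices$window)
  corr <- modality_context_correlation(midx, cidx)
  emit(data.frame(neuron = seq_along(midx), modality_index = midx,
                  modality_rank = rank(-midx, ties.method = "first"),
                  context_index = cidx), "neuron_indices.csv")
  emit(data.frame(r = corr$r, t = corr$t, p = corr$p, n = corr$n),
       "modality_context_correlation.csv")

  # optional network stage
  if (isTRUE(cfg$rnn$enabled)) {
    models <- rnn_train_models(cfg$rnn$n_models, seed0 = cfg$seed,
                               epochs = cfg$rnn$epochs, lr = cfg$rnn$lr,
                               batch_size = cfg$rnn$batch_size)
    perf <- data.frame(
      seed = vapply(models, function(m) m$seed, numeric(1)),
      performance = vapply(models, function(m) m$performance, numeric(1)),
      congruent = vapply(models, function(m) m$performance_congruent,
                         numeric(1)),
      incongruent = vapply(models, function(m) m$performance_incongruent,
                           numeric(1)))
    emit(perf, "rnn_performance.csv")
    pooled <- tryCatch(
      rnn_pooled_correlation(models, cfg$rnn$min_performance),
      error = function(e) NULL)
    if (!is.null(pooled)) {
      emit(data.frame(r = pooled$r, t = pooled$t, p = pooled$p,
                      n = pooled$n, n_models = pooled$n_models),
           "rnn_pooled_correlation.csv")
    }
  }

  manifest <- data.frame(file = basename(written),
                         path = written, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
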