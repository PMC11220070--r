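#' Specification of a synthetic population recording
#'
#' Defines the statistical structure of a simulated population: per-variable
#' one-dimensional coding subspaces (unit embedding vectors in neuron
#' space), response gains, temporal envelopes, context-gated suppression of
#' the irrelevant modality, and a noise model. The generator plants the
#' structure the population analyses assume — approximately orthogonal
#' stimulus/context/decision subspaces and a context-dependent reduction of
#' the irrelevant modality's signal — so every downstream estimator can be
#' tested against known ground truth.
#'
#' @param n_neurons Number of units.
#' @param time Trial time window in seconds relative to stimulus onset.
#' @param dt Sample interval in seconds.
#' @param baseline Baseline rate (Hz).
#' @param gains Named vector of response gains (Hz) for `visual`,
#'   `auditory`, `context`, `decision`.
#' @param angle_va Planted angle (degrees) between the visual and auditory
#'   embeddings; other pairs are orthogonal.
#' @param suppression_gamma Multiplier in \[0, 1\] on the irrelevant
#'   modality's gain once suppression is engaged; 1 disables suppression.
#' @param suppression_onset Time (s) at which suppression starts to ramp.
#' @param suppression_tau Suppression ramp time constant (s).
#' @param tau Response-onset ramp time constant (s).
#' @param stim_duration Stimulus duration (s).
#' @param decision_onset Time (s) at which decision-related activity ramps.
#' @param decision_persist If `TRUE` the decision trace persists to the end
#'   of the time window (memory trace); otherwise it ends with the trial.
#' @param noise `"gaussian_rate"` or `"poisson_counts"`.
#' @param noise_sd Gaussian rate noise s.d. (Hz).
#' @param preset `"mixed"` (random orthonormal embeddings, every neuron may
#'   carry several variables) or `"disjoint"` (each variable loads on its
#'   own block of neurons; exactly orthogonal by construction).
#' @param embed_seed Seed for drawing the embedding directions.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 60L,
                            time = c(-1.5, 3),
                            dt = 0.1,
                            baseline = 5,
                            gains = c(visual = 4, auditory = 4,
                                      context = 2, decision = 3),
                            angle_va = 90,
                            suppression_gamma = 1,
                            suppression_onset = 0.25,
                            suppression_tau = 0.5,
                            tau = 0.1,
                            stim_duration = 3,
                            decision_onset = 0.5,
                            decision_persist = FALSE,
                            noise = c("gaussian_rate", "poisson_counts"),
                            noise_sd = 2,
                            preset = c("mixed", "disjoint"),
                            embed_seed = 1L) {
  noise <- match.arg(noise)
  preset <- match.arg(preset)
  stopifnot(suppression_gamma >= 0, suppression_gamma <= 1,
            all(c("visual", "auditory", "context", "decision") %in%
                  names(gains)),
            n_neurons >= 4L)
  vars <- c("visual", "auditory", "context", "decision")
  emb <- matrix(0, n_neurons, 4L, dimnames = list(NULL, vars))
  if (preset == "disjoint") {
    blocks <- split(seq_len(n_neurons),
                    cut(seq_len(n_neurons), 4L, labels = FALSE))
    for (v in 1:4) {
      emb[blocks[[v]], v] <- 1 / sqrt(length(blocks[[v]]))
    }
    if (angle_va != 90) {
      stop("preset \"disjoint\" plants exactly orthogonal subspaces",
           call. = FALSE)
    }
  } else {
    old <- .Random.seed_save()
    set.seed(embed_seed)
    q <- qr.Q(qr(matrix(stats::rnorm(n_neurons * 4L), n_neurons, 4L)))
    .Random.seed_restore(old)
    theta <- angle_va * pi / 180
    emb[, "visual"] <- q[, 1L]
    emb[, "auditory"] <- cos(theta) * q[, 1L] + sin(theta) * q[, 2L]
    emb[, "context"] <- q[, 3L]
    emb[, "decision"] <- q[, 4L]
  }
  structure(list(
    n_neurons = n_neurons, time = time, dt = dt, baseline = baseline,
    gains = gains[vars], angle_va = angle_va,
    suppression_gamma = suppression_gamma,
    suppression_onset = suppression_onset,
    suppression_tau = suppression_tau, tau = tau,
    stim_duration = stim_duration, decision_onset = decision_onset,
    decision_persist = decision_persist, noise = noise,
    noise_sd = noise_sd, preset = preset, embeddings = emb
  ), class = "population_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Planted angle between two embedding directions
#'
#' Ground truth for angle-recovery tests: the arccos of the dot product of
#' the (unit-norm) embedding vectors.
#'
#' @param spec A [population_spec()].
#' @param var_a,var_b Variable names.
#' @return Angle in degrees.
#' @export
planted_angle <- function(spec, var_a, var_b) {
  ea <- spec$embeddings[, var_a]
  eb <- spec$embeddings[, var_b]
  na <- sqrt(sum(ea^2)); nb <- sqrt(sum(eb^2))
  if (na == 0 || nb == 0) {
    stop("embedding vector has zero norm", call. = FALSE)
  }
  acos(pmin(pmax(sum(ea * eb) / (na * nb), -1), 1)) * 180 / pi
}

.onset_ramp <- function(t, onset, tau, off = Inf) {
  ifelse(t > onset & t < off, 1 - exp(-(t - onset) / pmax(tau, 1e-9)), 0)
}

#' Generate a synthetic population tensor
#'
#' Expected rate per trial, neuron and time:
#' `baseline + sum_v gain_v * sign_v(trial) * envelope_v(t) * embedding_v`,
#' where the irrelevant modality's gain is multiplied by
#' `suppression_gamma` ramping in after `suppression_onset`. The context
#' signal is tonic (present through the whole window, including the
#' intertrial periods); stimulus envelopes rise at stimulus onset with time
#' constant `tau`; decision-related activity rises at `decision_onset` with
#' the sign of the trial's lick response.
#'
#' @param spec A [population_spec()].
#' @param trials Data frame with columns `visual`, `auditory`, `context`
#'   and optionally `lick` (defaults to the contextual target).
#' @param seed Integer seed for the noise draws.
#' @return A `population_tensor`: list with `rates`
#'   (trials x neurons x time), `time_s`, `trials`, `meta`.
#' @export
generate_population <- function(spec, trials, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"),
            all(c("visual", "auditory", "context") %in% names(trials)))
  time_s <- seq(spec$time[1], spec$time[2], by = spec$dt)
  n_tr <- nrow(trials)
  n_nr <- spec$n_neurons
  n_t <- length(time_s)
  lick <- if ("lick" %in% names(trials)) trials$lick else
    contextual_target(trials$visual, trials$auditory, trials$context)

  stim_env <- .onset_ramp(time_s, 0, spec$tau, spec$stim_duration)
  dec_off <- if (spec$decision_persist) Inf else spec$stim_duration
  dec_env <- .onset_ramp(time_s, spec$decision_onset, spec$tau, dec_off)
  sup_ramp <- .onset_ramp(time_s, spec$suppression_onset,
                          spec$suppression_tau)
  sup_mult <- 1 - (1 - spec$suppression_gamma) * sup_ramp

  signs <- cbind(
    visual = ifelse(trials$visual == 1, 1, -1),
    auditory = ifelse(trials$auditory == 1, 1, -1),
    context = ifelse(trials$context == "visual", 1, -1),
    decision = ifelse(lick == 1, 1, -1)
  )
  # per-trial x time gain modulation for each variable
  rel_v <- trials$context == "visual"
  W <- list()
  W$visual <- outer(signs[, "visual"] * spec$gains["visual"], stim_env)
  W$visual[!rel_v, ] <- W$visual[!rel_v, , drop = FALSE] *
    rep(sup_mult, each = sum(!rel_v))
  W$auditory <- outer(signs[, "auditory"] * spec$gains["auditory"], stim_env)
  W$auditory[rel_v, ] <- W$auditory[rel_v, , drop = FALSE] *
    rep(sup_mult, each = sum(rel_v))
  W$context <- outer(signs[, "context"] * spec$gains["context"],
                     rep(1, n_t))
  W$decision <- outer(signs[, "decision"] * spec$gains["decision"], dec_env)

  rates <- array(spec$baseline, dim = c(n_tr, n_nr, n_t))
  for (v in colnames(spec$embeddings)) {
    e <- spec$embeddings[, v]
    nz <- which(e != 0)
    for (j in nz) rates[, j, ] <- rates[, j, ] + W[[v]] * e[j]
  }
  set.seed(seed)
  n_clipped <- 0L
  if (spec$noise == "gaussian_rate") {
    rates <- rates + array(stats::rnorm(length(rates), 0, spec$noise_sd),
                           dim = dim(rates))
  } else {
    lam <- rates * spec$dt
    n_clipped <- sum(lam < 0)
    lam[lam < 0] <- 0
    rates <- array(stats::rpois(length(lam), lam) / spec$dt,
                   dim = dim(rates))
  }
  structure(list(
    rates = rates, time_s = time_s, trials = as.data.frame(trials),
    meta = list(spec = spec, seed = seed, standardized = FALSE,
                n_clipped = n_clipped)
  ), class = "population_tensor")
}

#' Construct a population tensor from components
#'
#' @param rates trials x neurons x time array.
#' @param time_s Strictly increasing, uniformly spaced time axis (s).
#' @param trials Trial table with one row per tensor trial.
#' @param meta Optional metadata list.
#' @return A `population_tensor`.
#' @export
population_tensor <- function(rates, time_s, trials, meta = list()) {
  stopifnot(length(dim(rates)) == 3L, dim(rates)[1] == nrow(trials),
            dim(rates)[3] == length(time_s))
  if (length(time_s) > 1L) {
    dts <- diff(time_s)
    stopifnot(all(dts > 0), max(abs(dts - dts[1])) < 1e-8)
  }
  structure(list(rates = rates, time_s = time_s,
                 trials = as.data.frame(trials), meta = meta),
            class = "population_tensor")
}

#' Time-axis indices covering a window
#'
#' @param tensor A `population_tensor`.
#' @param window `c(start, end)` in seconds (half-open: start <= t < end).
#' @return Integer indices into `tensor$time_s`.
#' @export
time_index <- function(tensor, window) {
  idx <- which(tensor$time_s >= window[1] & tensor$time_s < window[2])
  if (length(idx) == 0L) {
    stop("window contains no timepoints", call. = FALSE)
  }
  idx
}

#' @export
print.population_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf(
    "population_tensor: %d trials x %d neurons x %d timepoints (%.2f..%.2f s)%s\n",
    d[1], d[2], d[3], min(x$time_s), max(x$time_s),
    if (isTRUE(x$meta$standardized)) ", baseline-standardized" else ""))
  invisible(x)
}
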