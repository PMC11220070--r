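#' Convert spike events to instantaneous firing rates
#'
#' Counts spikes in sliding bins and smooths with a Gaussian kernel to
#' approximate single-trial instantaneous firing rates (IFR). Counts are
#' computed in `bin_ms` bins (half-open `[t, t + dt)`), convolved with a
#' Gaussian of `sigma_ms` truncated at 4 sigma and renormalized, and scaled
#' to Hz. At window edges the kernel is renormalized over the retained
#' support so no rate mass is attributed to unobserved time.
#'
#' @param events Data frame with columns `unit_id` and `time_s` (session
#'   clock, non-decreasing within unit).
#' @param trials Data frame with `t_stim_on_s` per trial.
#' @param bin_ms Count bin width (ms).
#' @param sigma_ms Gaussian smoothing s.d. (ms).
#' @param window Trial window (s) relative to stimulus onset.
#' @param units Optional unit ordering; defaults to sorted unique
#'   `events$unit_id`. Units without spikes keep all-zero rows.
#' @return A `population_tensor` (trials x units x bins) in Hz.
#' @export
events_to_ifr <- function(events, trials, bin_ms = 10, sigma_ms = 100,
                          window = c(-1.5, 3), units = NULL) {
  stopifnot(all(c("unit_id", "time_s") %in% names(events)),
            "t_stim_on_s" %in% names(trials))
  dt <- bin_ms / 1000
  sigma <- sigma_ms / 1000
  edges <- seq(window[1], window[2], by = dt)
  mids <- edges[-length(edges)] + dt / 2
  n_t <- length(mids)
  if (is.null(units)) units <- sort(unique(events$unit_id))
  n_u <- length(units)
  n_tr <- nrow(trials)

  half <- ceiling(4 * sigma / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  # edge renormalization: kernel weight actually retained at each bin
  support <- numeric(n_t)
  for (i in seq_len(n_t)) {
    lo <- max(1L, i - half); hi <- min(n_t, i + half)
    support[i] <- sum(kern[(lo - i + half + 1L):(hi - i + half + 1L)])
  }

  rates <- array(0, dim = c(n_tr, n_u, n_t))
  ev_by_unit <- split(events$time_s, factor(events$unit_id, levels = units))
  for (u in seq_len(n_u)) {
    ts <- ev_by_unit[[u]]
    if (length(ts) == 0L) next
    for (tr in seq_len(n_tr)) {
      rel <- ts - trials$t_stim_on_s[tr]
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel) == 0L) next
      counts <- tabulate(findInterval(rel, edges), nbins = n_t)
      sm <- rep(0, n_t)
      for (i in which(counts > 0)) {
        lo <- max(1L, i - half); hi <- min(n_t, i + half)
        sm[lo:hi] <- sm[lo:hi] +
          counts[i] * kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      }
      rates[tr, u, ] <- sm / support / dt
    }
  }
  population_tensor(rates, mids, trials,
                    meta = list(bin_ms = bin_ms, sigma_ms = sigma_ms,
                                units = units, standardized = FALSE))
}

#' Baseline z-scoring of a population tensor
#'
#' Standardizes each neuron by subtracting its mean prestimulus baseline
#' (time-averaged over `baseline`, then averaged over trials) and dividing
#' by its whole-trial standard deviation pooled across trials. Neurons with
#' zero variance are flagged and their s.d. replaced by 1 so the output
#' stays finite.
#'
#' @param tensor A `population_tensor`.
#' @param baseline Baseline window (s), default the prestimulus period.
#' @return A standardized `population_tensor`; `meta$baseline_mean`,
#'   `meta$trial_sd` and `meta$zero_sd_units` record the transformation.
#' @export
zscore_baseline <- function(tensor, baseline = c(-1.5, 0)) {
  stopifnot(inherits(tensor, "population_tensor"))
  if (baseline[1] < min(tensor$time_s) - 1e-9 ||
      baseline[2] > max(tensor$time_s) + 1e-9) {
    stop("baseline window outside the tensor time axis", call. = FALSE)
  }
  idx <- which(tensor$time_s >= baseline[1] & tensor$time_s < baseline[2])
  n_u <- dim(tensor$rates)[2]
  base_mean <- vapply(seq_len(n_u), function(j) {
    mean(tensor$rates[, j, idx])
  }, numeric(1))
  trial_sd <- vapply(seq_len(n_u), function(j) {
    stats::sd(as.vector(tensor$rates[, j, ]))
  }, numeric(1))
  zero_sd <- which(trial_sd == 0 | is.na(trial_sd))
  trial_sd[zero_sd] <- 1
  rates <- tensor$rates
  for (j in seq_len(n_u)) {
    rates[, j, ] <- (rates[, j, ] - base_mean[j]) / trial_sd[j]
  }
  meta <- tensor$meta
  meta$standardized <- TRUE
  meta$baseline_window <- baseline
  meta$baseline_mean <- base_mean
  meta$trial_sd <- trial_sd
  meta$zero_sd_units <- zero_sd
  population_tensor(rates, tensor$time_s, tensor$trials, meta)
}
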