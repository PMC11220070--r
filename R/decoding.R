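#' Stratified cross-validation fold assignment
#'
#' @param y Binary label vector.
#' @param folds Number of folds.
#' @param seed Seed for the (label-stratified) shuffle.
#' @return Integer fold id per observation.
#' @keywords internal
stratified_folds <- function(y, folds, seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  .Random.seed_restore(old)
  fold
}

.fit_logistic <- function(x, y, lambda) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = FALSE, intercept = TRUE)
}

#' Time-resolved linear decoders for a binary task variable
#'
#' Fits an independent logistic-regression classifier at every timepoint of
#' a population tensor, with stratified k-fold cross-validation for the
#' accuracy estimate. The decision vector (DV) at a timepoint is the
#' coefficient vector of the decoder fit on all selected trials — the
#' normal of the separating hyperplane; the intercept is kept for
#' prediction but excluded from all geometry. Weak L2 regularization keeps
#' the DV defined when classes are linearly separable.
#'
#' @param tensor A `population_tensor`.
#' @param labels Binary vector (0/1 or logical) per trial, or the name of a
#'   column in `tensor$trials`.
#' @param subset Optional logical/integer trial subset (applied before
#'   fitting, e.g. lick-only or consistent-only conditioning).
#' @param folds Number of CV folds.
#' @param min_per_class Minimum trials per class; below it the series is
#'   marked unavailable rather than silently fit.
#' @param lambda Ridge penalty (weak by default).
#' @param timepoints Optional indices into the time axis (default all).
#' @param seed Seed for fold assignment.
#' @return A `decoder_series`: list with `available`, `time_s`, `dv`
#'   (neurons x timepoints), `dv_unit` (unit-norm columns), `intercept`,
#'   `fold_acc` (folds x timepoints), `accuracy` (CV mean per timepoint),
#'   `acc_sem`, `fold`, `n_per_class`, `lambda`.
#' @export
fit_timepoint_decoders <- function(tensor, labels, subset = NULL,
                                   folds = 10L, min_per_class = 10L,
                                   lambda = 1e-3, timepoints = NULL,
                                   seed = 1L) {
  stopifnot(inherits(tensor, "population_tensor"))
  if (is.character(labels) && length(labels) == 1L) {
    labels <- tensor$trials[[labels]]
  }
  y <- as.integer(labels)
  keep <- seq_len(dim(tensor$rates)[1])
  if (!is.null(subset)) keep <- keep[subset]
  y <- y[keep]
  if (is.null(timepoints)) timepoints <- seq_along(tensor$time_s)
  n_class <- table(factor(y, levels = c(0L, 1L)))
  out <- list(available = TRUE, time_s = tensor$time_s[timepoints],
              n_per_class = as.integer(n_class), folds = folds,
              lambda = lambda, trials_used = keep)
  if (any(n_class < min_per_class)) {
    out$available <- FALSE
    class(out) <- "decoder_series"
    return(out)
  }
  fold <- stratified_folds(y, folds, seed)
  n_t <- length(timepoints)
  p <- dim(tensor$rates)[2]
  dv <- matrix(NA_real_, p, n_t)
  icpt <- numeric(n_t)
  fold_acc <- matrix(NA_real_, folds, n_t)
  for (k in seq_len(n_t)) {
    X <- tensor$rates[keep, , timepoints[k], drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = p)
    fit <- .fit_logistic(X, y, lambda)
    dv[, k] <- as.numeric(fit$beta)
    icpt[k] <- fit$a0
    for (f in seq_len(folds)) {
      tr <- fold != f
      ffit <- .fit_logistic(X[tr, , drop = FALSE], y[tr], lambda)
      pred <- as.integer(stats::predict(ffit, X[!tr, , drop = FALSE],
                                        type = "response") > 0.5)
      fold_acc[f, k] <- mean(pred == y[!tr])
    }
  }
  nrm <- sqrt(colSums(dv^2))
  out$dv <- dv
  out$dv_unit <- sweep(dv, 2, pmax(nrm, 1e-12), "/")
  out$intercept <- icpt
  out$fold_acc <- fold_acc
  out$accuracy <- colMeans(fold_acc)
  out$acc_sem <- apply(fold_acc, 2, stats::sd) / sqrt(folds)
  out$fold <- fold
  class(out) <- "decoder_series"
  out
}

#' @export
print.decoder_series <- function(x, ...) {
  if (!x$available) {
    cat("decoder_series: unavailable (class below minimum trial count)\n")
  } else {
    cat(sprintf(
      "decoder_series: %d timepoints, %d-fold CV, mean accuracy %.3f\n",
      length(x$time_s), x$folds, mean(x$accuracy)))
  }
  invisible(x)
}

#' Angle between two decision vectors
#'
#' Arccos of the dot product of the unit-normalized DVs, in degrees. The
#' angle is symmetric and invariant to positive rescaling of either DV.
#'
#' @param dv1,dv2 Numeric vectors (same length, non-zero).
#' @return Angle in degrees in \[0, 180\].
#' @export
dv_angle <- function(dv1, dv2) {
  n1 <- sqrt(sum(dv1^2)); n2 <- sqrt(sum(dv2^2))
  if (n1 == 0 || n2 == 0) {
    stop("cannot compute an angle with a zero decision vector",
         call. = FALSE)
  }
  acos(pmin(pmax(sum(dv1 * dv2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Two-dimensional DV subspace
#'
#' Orthonormal basis spanning two DVs: axis 1 parallel to `dv1`, axis 2 the
#' component of `dv2` orthogonal to `dv1` (Gram-Schmidt, the QR
#' construction), normalized. Trial activity projects into the plane by dot
#' products with the axes.
#'
#' @param dv1,dv2 Linearly independent DVs.
#' @param tol Degeneracy tolerance on the residual norm fraction.
#' @return List with `axis1`, `axis2` (unit vectors) and
#'   `project(x)`, mapping a neurons-vector or trials x neurons matrix to
#'   planar coordinates.
#' @export
subspace_2d <- function(dv1, dv2, tol = 1e-8) {
  a1 <- dv1 / sqrt(sum(dv1^2))
  resid <- dv2 - sum(dv2 * a1) * a1
  rn <- sqrt(sum(resid^2))
  if (rn < tol * sqrt(sum(dv2^2))) {
    stop("decision vectors are (near) parallel: plane degenerate",
         call. = FALSE)
  }
  a2 <- resid / rn
  project <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    cbind(axis1 = as.numeric(x %*% a1), axis2 = as.numeric(x %*% a2))
  }
  list(axis1 = a1, axis2 = a2, project = project)
}

#' Project population activity onto a decision vector
#'
#' Computes `y(t) = d . x(t)` per trial. When `dv` is a `decoder_series`
#' the DV is averaged over `train_window` timepoints and unit-normalized
#' before projecting, supporting cross-time projections (train early, test
#' across the trial).
#'
#' @param dv A `decoder_series` or numeric vector.
#' @param tensor A `population_tensor`.
#' @param train_window Window (s) over which to average the DV (required
#'   for a `decoder_series`).
#' @param project_window Window (s) to project; default the whole axis.
#' @param subset Optional trial subset.
#' @return List with `y` (trials x timepoints), `time_s`, `dv` used.
#' @export
project_activity <- function(dv, tensor, train_window = NULL,
                             project_window = NULL, subset = NULL) {
  if (inherits(dv, "decoder_series")) {
    if (!dv$available) stop("decoder series unavailable", call. = FALSE)
    if (is.null(train_window)) {
      stop("`train_window` is required to average a decoder series",
           call. = FALSE)
    }
    idx <- which(dv$time_s >= train_window[1] & dv$time_s < train_window[2])
    if (length(idx) == 0L) stop("empty train window", call. = FALSE)
    d <- rowMeans(dv$dv[, idx, drop = FALSE])
  } else {
    d <- as.numeric(dv)
  }
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("zero decision vector", call. = FALSE)
  d <- d / nrm
  kidx <- if (is.null(project_window)) seq_along(tensor$time_s) else
    time_index(tensor, project_window)
  keep <- seq_len(dim(tensor$rates)[1])
  if (!is.null(subset)) keep <- keep[subset]
  y <- vapply(kidx, function(k) {
    as.numeric(tensor$rates[keep, , k, drop = TRUE] %*% d)
  }, numeric(length(keep)))
  if (is.null(dim(y))) y <- matrix(y, nrow = length(keep))
  list(y = y, time_s = tensor$time_s[kidx], dv = d)
}

#' Shuffled-label chance level for a decoder
#'
#' Repeats the cross-validated decoding with labels drawn from a fair
#' Bernoulli distribution and returns the effective chance threshold: the
#' shuffled mean accuracy plus a one-sided confidence margin combining the
#' across-shuffle and across-fold standard errors.
#'
#' @inheritParams fit_timepoint_decoders
#' @param n_shuffles Number of independent label randomizations.
#' @param conf One-sided confidence level for the threshold.
#' @return List with `mean`, `sem_shuffle`, `sem_cv`, `threshold`
#'   (vectors per timepoint) and `per_shuffle` accuracies.
#' @export
chance_level <- function(tensor, labels, subset = NULL, n_shuffles = 40L,
                         folds = 10L, lambda = 1e-3, timepoints = NULL,
                         conf = 0.95, seed = 1L) {
  keep <- seq_len(dim(tensor$rates)[1])
  if (!is.null(subset)) keep <- keep[subset]
  n <- length(keep)
  if (is.null(timepoints)) timepoints <- seq_along(tensor$time_s)
  old <- .Random.seed_save()
  set.seed(seed)
  acc <- array(NA_real_, c(n_shuffles, length(timepoints)))
  semcv <- array(NA_real_, c(n_shuffles, length(timepoints)))
  for (s in seq_len(n_shuffles)) {
    repeat {
      ys <- stats::rbinom(n, 1L, 0.5)
      if (min(table(factor(ys, levels = 0:1))) >= folds) break
    }
    yfull <- integer(dim(tensor$rates)[1])
    yfull[keep] <- ys
    ds <- fit_timepoint_decoders(tensor, yfull, subset = keep,
                                 folds = folds, min_per_class = folds,
                                 lambda = lambda, timepoints = timepoints,
                                 seed = seed + s)
    acc[s, ] <- ds$accuracy
    semcv[s, ] <- ds$acc_sem
  }
  .Random.seed_restore(old)
  m <- colMeans(acc)
  sem_sh <- apply(acc, 2, stats::sd) / sqrt(n_shuffles)
  sem_cv <- colMeans(semcv)
  z <- stats::qnorm(conf)
  list(mean = m, sem_shuffle = sem_sh, sem_cv = sem_cv,
       threshold = m + z * sqrt(sem_sh^2 + sem_cv^2), per_shuffle = acc)
}

#' Autocorrelation-based block averaging of a time series
#'
#' Computes the autocorrelation of an accuracy (or other) time series at
#' native-resolution lags, takes the first zero-crossing lag as the block
#' width, and averages the series in non-overlapping blocks over `range`.
#' If the autocorrelation never reaches zero the configured fallback width
#' is used and flagged.
#'
#' @param values Numeric series on a uniform time grid.
#' @param time_s Time axis (s).
#' @param width Block width (s); `NULL` to estimate from the
#'   autocorrelation zero-crossing.
#' @param range Interval (s) over which blocks are laid out.
#' @param fallback_width Width used when no zero-crossing exists.
#' @return List with `width`, `from_autocorr`, `fallback`, `block_start`,
#'   `block_mean`, `n_blocks`.
#' @export
block_average <- function(values, time_s, width = NULL,
                          range = c(0.6, 3), fallback_width = 0.6) {
  stopifnot(length(values) == length(time_s))
  dt <- stats::median(diff(time_s))
  fallback <- FALSE
  from_ac <- FALSE
  if (is.null(width)) {
    v <- values - mean(values)
    if (stats::sd(values) == 0) {
      width <- fallback_width
      fallback <- TRUE
    } else {
      ac <- stats::acf(values, lag.max = length(values) - 1L,
                       plot = FALSE)$acf[, 1, 1]
      zc <- which(ac <= 0)
      if (length(zc) == 0L) {
        width <- fallback_width
        fallback <- TRUE
      } else {
        width <- (zc[1L] - 1L) * dt
        width <- max(width, dt)
        from_ac <- TRUE
      }
    }
  }
  starts <- seq(range[1], range[2] - width + 1e-9, by = width)
  bm <- vapply(starts, function(s) {
    idx <- which(time_s >= s & time_s < s + width)
    if (length(idx) == 0L) NA_real_ else mean(values[idx])
  }, numeric(1))
  list(width = width, from_autocorr = from_ac, fallback = fallback,
       block_start = starts, block_mean = bm, n_blocks = length(starts))
}

#' Relevant-minus-irrelevant suppression profile
#'
#' Per-timepoint difference between the decoding accuracy of a stimulus in
#' its relevant and irrelevant context, block-averaged in fixed windows in
#' the late-trial interval, with a two-sided paired t test across blocks.
#'
#' @param relevant,irrelevant `decoder_series` for the same variable on a
#'   common time axis.
#' @param range Interval (s) for block averaging.
#' @param width Block width (s).
#' @return A `suppression_profile`: list with `available`, `time_s`,
#'   `difference`, `blocks_relevant`, `blocks_irrelevant`,
#'   `block_difference`, `t`, `p`, `df`.
#' @export
suppression_metric <- function(relevant, irrelevant, range = c(0.6, 3),
                               width = 0.6) {
  out <- list(available = relevant$available && irrelevant$available)
  class(out) <- "suppression_profile"
  if (!out$available) return(out)
  stopifnot(length(relevant$time_s) == length(irrelevant$time_s),
            max(abs(relevant$time_s - irrelevant$time_s)) < 1e-9)
  diff <- relevant$accuracy - irrelevant$accuracy
  br <- block_average(relevant$accuracy, relevant$time_s, width = width,
                      range = range)
  bi <- block_average(irrelevant$accuracy, irrelevant$time_s, width = width,
                      range = range)
  bd <- br$block_mean - bi$block_mean
  tt <- stats::t.test(br$block_mean, bi$block_mean, paired = TRUE)
  out$time_s <- relevant$time_s
  out$difference <- diff
  out$blocks_relevant <- br$block_mean
  out$blocks_irrelevant <- bi$block_mean
  out$block_start <- br$block_start
  out$block_difference <- bd
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}

#' Edge-versus-middle cross-validation for the context decoder
#'
#' Drift control for context decoding: context blocks occupy the beginning
#' and end of a session, so slow drifts masquerade as context signal. The
#' scheme trains on a fixed set of 20 trials (10 per context) taken at the
#' session edges and tests on middle trials (two folds of 5 per context),
#' then reciprocally trains on middle trials and tests at the edges. A real
#' and stationary context signal gives matching accuracy time courses;
#' drift inflates the edge-trained direction.
#'
#' @param tensor A `population_tensor` whose trials are in session order.
#' @param context Binary context labels per trial (0/1), or column name.
#' @param n_train Total training trials (split evenly across contexts).
#' @param n_test_fold Test trials per context per fold.
#' @param folds_test Number of test folds (fixed at 2 in the standard
#'   scheme).
#' @param lambda,seed As in [fit_timepoint_decoders()].
#' @return List with `available`, `edge_trained` and `middle_trained`
#'   accuracy matrices (folds x timepoints), mean `accuracy_edge`,
#'   `accuracy_middle`, `time_s`, and a paired two-sided t test on
#'   block-averaged differences (`t`, `p`).
#' @export
fit_context_decoder_edgewise <- function(tensor, context, n_train = 20L,
                                         n_test_fold = 5L, folds_test = 2L,
                                         lambda = 1e-3, seed = 1L) {
  if (is.character(context) && length(context) == 1L) {
    context <- tensor$trials[[context]]
  }
  y <- as.integer(context)
  per_ctx <- n_train %/% 2L
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  need <- per_ctx + folds_test * n_test_fold
  if (length(i0) < need || length(i1) < need) {
    return(structure(list(available = FALSE), class = "edgewise_context"))
  }
  # session layout: context 0 first, context 1 second; edges are the
  # session start and end, middle flanks the context switch
  edge <- c(utils::head(i0, per_ctx), utils::tail(i1, per_ctx))
  mid0 <- utils::tail(i0, folds_test * n_test_fold)
  mid1 <- utils::head(i1, folds_test * n_test_fold)
  # reciprocal: train on middle, test at the outermost edge trials
  middle <- c(mid0, mid1)
  edge_test0 <- utils::head(i0, folds_test * n_test_fold)
  edge_test1 <- utils::tail(i1, folds_test * n_test_fold)

  n_t <- length(tensor$time_s)
  run_dir <- function(train_idx, test0, test1) {
    acc <- matrix(NA_real_, folds_test, n_t)
    for (k in seq_len(n_t)) {
      X <- tensor$rates[train_idx, , k, drop = TRUE]
      fit <- .fit_logistic(X, y[train_idx], lambda)
      for (f in seq_len(folds_test)) {
        sel <- c(test0[seq((f - 1L) * n_test_fold + 1L, f * n_test_fold)],
                 test1[seq((f - 1L) * n_test_fold + 1L, f * n_test_fold)])
        pred <- as.integer(stats::predict(
          fit, tensor$rates[sel, , k, drop = TRUE],
          type = "response") > 0.5)
        acc[f, k] <- mean(pred == y[sel])
      }
    }
    acc
  }
  acc_edge <- run_dir(edge, mid0, mid1)
  acc_mid <- run_dir(middle, edge_test0, edge_test1)
  ae <- colMeans(acc_edge); am <- colMeans(acc_mid)
  be <- block_average(ae, tensor$time_s, width = 0.6,
                      range = c(min(tensor$time_s), max(tensor$time_s)))
  bm <- block_average(am, tensor$time_s, width = 0.6,
                      range = c(min(tensor$time_s), max(tensor$time_s)))
  ok <- !is.na(be$block_mean) & !is.na(bm$block_mean)
  tt <- stats::t.test(be$block_mean[ok], bm$block_mean[ok], paired = TRUE)
  structure(list(available = TRUE, time_s = tensor$time_s,
                 edge_trained = acc_edge, middle_trained = acc_mid,
                 accuracy_edge = ae, accuracy_middle = am,
                 t = unname(tt$statistic), p = tt$p.value),
            class = "edgewise_context")
}
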