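#' Single-trial estimation settings
#'
#' Controls how a per-channel response value is estimated for each trial
#' before multivariate classification. The trial window runs from
#' `prestim_s` seconds before block onset to `poststim_s` seconds after
#' block offset. Within the window each channel's time course is
#' optionally z-normalized (default on), then an ordinary-least-squares
#' GLM with a constant, an optional linear trend, and one HRF-convolved
#' single-trial boxcar is fitted. The reported estimate is the main
#' predictor's beta (default), its t value, or the percent-signal beta
#' `100 * beta_main / beta_constant`.
#'
#' @param prestim_s seconds before trial onset included in the window.
#' @param poststim_s seconds after trial offset included in the window.
#' @param kind `"beta"` (default), `"t"`, or `"percent"`.
#' @param z_normalize z-normalize each channel window (default `TRUE`).
#' @param include_trend add the linear-trend confound predictor.
#' @param signal `"hbo"` (default), `"hb"`, or `"both"` (features of both
#'   chromophores concatenated).
#' @param hrf_params HRF overrides, see [hrf_double_gamma()].
#' @return an object of class `"trial_estimation_spec"`.
#' @export
trial_estimation_spec <- function(prestim_s = 2, poststim_s = 12,
                                  kind = c("beta", "t", "percent"),
                                  z_normalize = TRUE, include_trend = FALSE,
                                  signal = c("hbo", "hb", "both"),
                                  hrf_params = list()) {
  structure(
    list(
      prestim_s = prestim_s, poststim_s = poststim_s,
      kind = match.arg(kind), z_normalize = z_normalize,
      include_trend = include_trend, signal = match.arg(signal),
      hrf_params = hrf_params
    ),
    class = "trial_estimation_spec"
  )
}

#' Estimate one trial's per-channel responses
#'
#' @param conc matrix (samples x channels) of a preprocessed
#'   concentration time course (one chromophore).
#' @param trial length-2 vector `c(onset_s, offset_s)` of the trial block.
#' @param fs sampling rate in Hz.
#' @param spec a [trial_estimation_spec()].
#' @return numeric vector, one estimate per channel; attribute
#'   `"flagged"` marks zero-variance channels whose feature was set to 0.
#' @export
estimate_trial <- function(conc, trial, fs, spec = trial_estimation_spec()) {
  conc <- as.matrix(conc)
  n <- nrow(conc)
  w0 <- floor((trial[1L] - spec$prestim_s) * fs)
  w1 <- floor((trial[2L] + spec$poststim_s) * fs) - 1L
  w0 <- max(w0, 0L)
  w1 <- min(w1, n - 1L)
  if (w1 - w0 + 1L < 4L) stop("trial window has fewer than 4 samples")
  idx <- seq.int(w0 + 1L, w1 + 1L)
  Yw <- conc[idx, , drop = FALSE]
  flagged <- rep(FALSE, ncol(Yw))
  if (spec$z_normalize) {
    mu <- colMeans(Yw)
    sdv <- apply(Yw, 2L, stats::sd)
    flagged <- sdv == 0 | !is.finite(sdv)
    sdv[flagged] <- 1
    Yw <- sweep(sweep(Yw, 2L, mu), 2L, sdv, "/")
    Yw[, flagged] <- 0
  }
  # within-window design: single-trial boxcar, causally HRF-convolved
  t_s <- (w0:w1) / fs
  box <- t_s >= trial[1L] & t_s < trial[2L]
  main <- convolve_boxcar_hrf(box, fs, spec$hrf_params)
  Xw <- cbind(
    main = main,
    constant = rep(1, length(idx)),
    if (spec$include_trend) seq(0, 1, length.out = length(idx))
  )
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw)) {
    warning("singular single-trial design; trial dropped")
    return(NULL)
  }
  beta <- qr.coef(qrx, Yw)
  est <- switch(spec$kind,
    beta = beta[1L, ],
    t = {
      res <- Yw - Xw %*% beta
      dfree <- nrow(Xw) - ncol(Xw)
      sigma2 <- colSums(res^2) / dfree
      vmain <- chol2inv(qr.R(qrx))[1L, 1L]
      tv <- beta[1L, ] / sqrt(vmain * sigma2)
      tv[!is.finite(tv)] <- 0
      tv
    },
    percent = {
      const <- beta[2L, ]
      small <- abs(const) < 1e-8
      if (any(small)) {
        warning("constant beta ~ 0 (z-normalized data?); falling back to raw beta")
      }
      out <- 100 * beta[1L, ] / const
      out[small] <- beta[1L, small]
      out
    }
  )
  est[flagged] <- 0
  attr(est, "flagged") <- flagged
  est
}

#' Build a single-trial training set from completed runs
#'
#' One feature pattern per trial per run: the per-channel single-trial
#' estimates, labeled with the trial's condition and its run.
#'
#' @param runs list of runs; each run is a list with elements `hbo`,
#'   `hb` (samples x channels matrices, e.g. from [stream_convert()])
#'   and `protocol`.
#' @param spec a [trial_estimation_spec()].
#' @param conditions condition names to use as classes; defaults to all
#'   conditions of the first run. Must exist in every run.
#' @param channels channel indices to include (the channel mask).
#' @return an object of class `"trial_patterns"`: `features` matrix
#'   (patterns x features), factor `label`, integer `run`, `onset_s`,
#'   and the spec.
#' @export
build_training_set <- function(runs, spec = trial_estimation_spec(),
                               conditions = NULL, channels = NULL) {
  if (!length(runs)) stop("no runs given")
  if (is.null(conditions)) conditions <- names(runs[[1L]]$protocol$conditions)
  for (r in runs) {
    if (!all(conditions %in% names(r$protocol$conditions))) {
      stop("conditions mismatch across runs")
    }
  }
  if (!is.null(channels) && length(channels) == 0L) stop("empty channel mask")
  feats <- list()
  labels <- character(0)
  run_id <- integer(0)
  onsets <- numeric(0)
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    fs <- run$protocol$sampling_rate_hz
    sel <- function(m) {
      m <- as.matrix(m)
      if (is.null(channels)) m else m[, channels, drop = FALSE]
    }
    trials <- do.call(rbind, lapply(conditions, function(cn) {
      iv <- condition_trials(run$protocol, cn)
      if (nrow(iv)) cbind(iv, cond = match(cn, conditions)) else NULL
    }))
    trials <- trials[order(trials[, 1L]), , drop = FALSE]
    for (k in seq_len(nrow(trials))) {
      est <- switch(spec$signal,
        hbo = estimate_trial(sel(run$hbo), trials[k, 1:2], fs, spec),
        hb = estimate_trial(sel(run$hb), trials[k, 1:2], fs, spec),
        both = {
          a <- estimate_trial(sel(run$hbo), trials[k, 1:2], fs, spec)
          b <- estimate_trial(sel(run$hb), trials[k, 1:2], fs, spec)
          if (is.null(a) || is.null(b)) NULL else c(a, b)
        }
      )
      if (is.null(est)) next
      feats[[length(feats) + 1L]] <- as.numeric(est)
      labels <- c(labels, conditions[trials[k, 3L]])
      run_id <- c(run_id, ri)
      onsets <- c(onsets, trials[k, 1L])
    }
  }
  structure(
    list(
      features = do.call(rbind, feats),
      label = factor(labels, levels = conditions),
      run = run_id, onset_s = onsets, spec = spec
    ),
    class = "trial_patterns"
  )
}

#' @export
print.trial_patterns <- function(x, ...) {
  cat(sprintf(
    "trial patterns: %d trials x %d features, %d class(es), %d run(s)\n",
    nrow(x$features), ncol(x$features), nlevels(x$label), length(unique(x$run))
  ))
  print(table(run = x$run, class = x$label))
  invisible(x)
}

#' Per-class mean patterns
#'
#' The class-average rows shown under a training-pattern plot: mean
#' feature vector per class.
#'
#' @param patterns a [build_training_set()] result.
#' @return matrix (classes x features).
#' @export
class_mean_patterns <- function(patterns) {
  t(vapply(
    levels(patterns$label),
    function(cl) colMeans(patterns$features[patterns$label == cl, , drop = FALSE]),
    numeric(ncol(patterns$features))
  ))
}

#' Train a multiclass linear SVM on trial patterns
#'
#' One-vs-one linear support vector machine (cost 1 by default) over the
#' single-trial feature vectors.
#'
#' @param patterns a `"trial_patterns"` object (optionally subset).
#' @param cost SVM cost parameter.
#' @param kernel kernel name passed to [e1071::svm()].
#' @return an object of class `"nirs_svm"`.
#' @export
train_classifier <- function(patterns, cost = 1, kernel = "linear") {
  y <- droplevels(patterns$label)
  if (nlevels(y) < 2L) stop("training set has fewer than 2 classes")
  if (any(table(y) < 2L)) stop("need at least 2 patterns per class")
  model <- e1071::svm(patterns$features, y, kernel = kernel, cost = cost,
                      scale = FALSE)
  structure(
    list(model = model, classes = levels(y),
         n_features = ncol(patterns$features),
         runs_used = sort(unique(patterns$run)), spec = patterns$spec),
    class = "nirs_svm"
  )
}

#' @export
print.nirs_svm <- function(x, ...) {
  cat(sprintf(
    "linear SVM: %d class(es) [%s], %d feature(s), trained on run(s) %s\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    x$n_features, paste(x$runs_used, collapse = ", ")
  ))
  invisible(x)
}

#' @export
predict.nirs_svm <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "trial_patterns")) newdata$features else
    matrix(as.numeric(newdata), ncol = object$n_features)
  if (ncol(feats) != object$n_features) stop("feature dimension mismatch")
  stats::predict(object$model, feats)
}

subset_patterns <- function(patterns, keep) {
  patterns$features <- patterns$features[keep, , drop = FALSE]
  patterns$label <- patterns$label[keep]
  patterns$run <- patterns$run[keep]
  patterns$onset_s <- patterns$onset_s[keep]
  patterns
}

#' Leave-one-run-out cross-validation
#'
#' Each fold trains on all runs but one and tests on the held-out run.
#'
#' @param patterns a [build_training_set()] result spanning >= 2 runs.
#' @param cost,kernel classifier settings, see [train_classifier()].
#' @return list with `fold_runs`, per-fold `accuracy`, and
#'   `mean_accuracy` (proportions in 0..1).
#' @export
cross_validate <- function(patterns, cost = 1, kernel = "linear") {
  runs <- sort(unique(patterns$run))
  if (length(runs) < 2L) stop("leave-one-run-out needs at least 2 runs")
  acc <- vapply(runs, function(r) {
    fit <- train_classifier(subset_patterns(patterns, patterns$run != r),
                            cost = cost, kernel = kernel)
    test <- subset_patterns(patterns, patterns$run == r)
    mean(predict(fit, test) == test$label)
  }, numeric(1))
  list(fold_runs = runs, accuracy = acc, mean_accuracy = mean(acc))
}

#' Held-out run accuracy
#'
#' Trains on the given runs and reports accuracy on one test run — the
#' typical offline evaluation of a decoder before real-time use.
#'
#' @param patterns a [build_training_set()] result.
#' @param train_runs run IDs to train on.
#' @param test_run run ID to test on.
#' @inheritParams cross_validate
#' @return accuracy as a proportion in 0..1.
#' @export
holdout_accuracy <- function(patterns, train_runs, test_run, cost = 1,
                             kernel = "linear") {
  fit <- train_classifier(subset_patterns(patterns, patterns$run %in% train_runs),
                          cost = cost, kernel = kernel)
  test <- subset_patterns(patterns, patterns$run == test_run)
  mean(predict(fit, test) == test$label)
}

#' Permutation test of decoding accuracy
#'
#' Builds an empirical null for the leave-one-run-out accuracy: in each
#' permutation the class labels are shuffled within each training run,
#' the classifier is retrained per fold, and accuracy on the held-out
#' run is recomputed against the true labels. The p value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param patterns a [build_training_set()] result spanning >= 2 runs.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the label shuffles.
#' @inheritParams cross_validate
#' @return an object of class `"nirs_permtest"`: `observed` accuracy,
#'   `null` accuracies, `p_value`, and `null_q95` (the empirical 95th
#'   percentile of the null).
#' @export
permutation_test <- function(patterns, n_perm = 1000L, seed = NULL,
                             cost = 1, kernel = "linear") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- cross_validate(patterns, cost = cost, kernel = kernel)$mean_accuracy
  runs <- sort(unique(patterns$run))
  null_acc <- vapply(seq_len(n_perm), function(i) {
    shuffled <- patterns
    for (r in runs) {
      idx <- which(shuffled$run == r)
      shuffled$label[idx] <- shuffled$label[sample(idx)]
    }
    acc <- vapply(runs, function(r) {
      fit <- train_classifier(subset_patterns(shuffled, shuffled$run != r),
                              cost = cost, kernel = kernel)
      test_idx <- patterns$run == r
      test <- subset_patterns(patterns, test_idx) # true labels for testing
      mean(predict(fit, test) == test$label)
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  structure(
    list(
      observed = observed, null = null_acc,
      p_value = (1 + sum(null_acc >= observed)) / (n_perm + 1),
      null_q95 = unname(stats::quantile(null_acc, 0.95)),
      n_perm = n_perm
    ),
    class = "nirs_permtest"
  )
}

#' @export
print.nirs_permtest <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed accuracy %.1f%%, null mean %.1f%%, 95th pct %.2f%%, p = %.4g (%d permutations)\n",
    100 * x$observed, 100 * mean(x$null), 100 * x$null_q95, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' Export trial patterns
#'
#' `write_patterns_csv()` writes a plain CSV (label, run, onset_s,
#' feature columns). `write_patterns_sparse()` writes the de-facto
#' sparse classifier text format, one `label index:value ...` line per
#' pattern.
#'
#' @param patterns a `"trial_patterns"` object.
#' @param path output path.
#' @export
write_patterns_csv <- function(patterns, path) {
  df <- data.frame(
    label = patterns$label, run = patterns$run, onset_s = patterns$onset_s,
    patterns$features
  )
  names(df)[-(1:3)] <- paste0("f", seq_len(ncol(patterns$features)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns_csv
#' @export
write_patterns_sparse <- function(patterns, path) {
  lines <- vapply(seq_len(nrow(patterns$features)), function(i) {
    v <- patterns$features[i, ]
    nz <- which(v != 0)
    paste(
      as.integer(patterns$label[i]),
      paste(sprintf("%d:%.10g", nz, v[nz]), collapse = " ")
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
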