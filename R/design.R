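#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used for all boxcar convolutions: a gamma-density
#' peak minus a scaled gamma-density undershoot, normalized to unit peak.
#' Defaults: peak at 6 s, undershoot at 16 s, peak:undershoot ratio 6,
#' support truncated at 32 s.
#'
#' @param t_s time in seconds (vector).
#' @param peak_s time-to-peak of the positive lobe.
#' @param undershoot_s time-to-peak of the undershoot.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param duration_s truncation of the kernel support.
#' @return HRF values at `t_s`, unit peak.
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 6,
                             duration_s = 32) {
  # gamma densities with shape a, scale 1: mode at a - 1
  h <- stats::dgamma(t_s, shape = peak_s + 1, scale = 1) -
    stats::dgamma(t_s, shape = undershoot_s + 1, scale = 1) / ratio
  h[t_s < 0 | t_s > duration_s] <- 0
  pk <- stats::dgamma(peak_s, shape = peak_s + 1, scale = 1) -
    stats::dgamma(peak_s, shape = undershoot_s + 1, scale = 1) / ratio
  h / pk
}

#' Convolve a boxcar with the canonical HRF
#'
#' Causal convolution of a 0/1 boxcar with [hrf_double_gamma()] sampled
#' at `fs`, truncated to the boxcar's length and rescaled to unit peak
#' (so a regression beta on the resulting predictor is directly the
#' response amplitude in signal units). The same routine builds GLM
#' predictors and the simulator's ground-truth responses.
#'
#' @param boxcar logical or 0/1 numeric vector.
#' @param fs sampling rate in Hz.
#' @param hrf_params list of overrides passed to [hrf_double_gamma()].
#' @return numeric vector of the same length as `boxcar`.
#' @export
convolve_boxcar_hrf <- function(boxcar, fs, hrf_params = list()) {
  x <- as.numeric(boxcar)
  n <- length(x)
  dur <- if (!is.null(hrf_params$duration_s)) hrf_params$duration_s else 32
  t_h <- seq(0, dur, by = 1 / fs)
  h <- do.call(hrf_double_gamma, c(list(t_s = t_h), hrf_params))
  # direct (non-FFT) causal convolution: exact zeros before onset
  m <- length(h)
  xa <- c(rep(0, m - 1L), x)
  y <- as.numeric(stats::filter(xa, h, method = "convolution", sides = 1L))[m:(m + n - 1L)]
  m <- max(abs(y))
  if (m > 0) y <- y / m
  y
}

#' Build a GLM design matrix from a protocol
#'
#' One HRF-convolved boxcar predictor per condition, a constant column,
#' and optionally a linear trend column (spanning 0..1 over the series).
#'
#' @param protocol a [protocol()].
#' @param n_samples number of rows; defaults to the full protocol.
#' @param include_trend add a linear-trend confound column.
#' @param hrf_params HRF parameter overrides, see [hrf_double_gamma()].
#' @return numeric matrix (samples x predictors) with column names; task
#'   predictors first, then `"constant"` and optionally `"trend"`.
#'   Attribute `"task_columns"` marks the condition predictors.
#' @export
build_design <- function(protocol, n_samples = protocol_n_samples(protocol),
                         include_trend = FALSE, hrf_params = list()) {
  fs <- protocol$sampling_rate_hz
  nms <- names(protocol$conditions)
  if (length(nms) == 0L) warning("protocol has no conditions; design holds confounds only")
  cols <- lapply(nms, function(nm) {
    convolve_boxcar_hrf(condition_mask(protocol, nm, n_samples), fs, hrf_params)
  })
  X <- cbind(
    if (length(cols)) do.call(cbind, cols),
    constant = rep(1, n_samples),
    if (include_trend) seq(0, 1, length.out = n_samples)
  )
  colnames(X) <- c(nms, "constant", if (include_trend) "trend")
  attr(X, "task_columns") <- seq_along(nms)
  X
}
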