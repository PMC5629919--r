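#' Causal incremental detrending of raw data
#'
#' At each sample `t`, subtracts the ordinary-least-squares line fitted
#' to all samples received so far (0..t). The first sample passes
#' through unchanged (a line is undetermined by one point); from the
#' second sample on the running fit is exact, so a constant input maps
#' to 0 from the second sample and a pure linear trend is removed
#' entirely. Implemented from running sums, so the per-sample cost is
#' constant.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param state optional running-sum state from a previous call, to
#'   continue a stream.
#' @return list with `y` (detrended, same shape as `x`) and `state`.
#' @export
detrend_stream <- function(x, state = NULL) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  nch <- ncol(x)
  if (is.null(state)) {
    state <- list(n = 0, st = 0, stt = 0, sy = numeric(nch), sty = numeric(nch))
  }
  y <- x
  for (i in seq_len(nrow(x))) {
    ti <- state$n # 0-based time index of this sample
    state$n <- state$n + 1
    state$st <- state$st + ti
    state$stt <- state$stt + ti * ti
    state$sy <- state$sy + x[i, ]
    state$sty <- state$sty + ti * x[i, ]
    n <- state$n
    den <- n * state$stt - state$st^2
    if (n < 2 || den <= 0) {
      y[i, ] <- x[i, ] # line undetermined: pass through
    } else {
      slope <- (n * state$sty - state$st * state$sy) / den
      intercept <- (state$sy - slope * state$st) / n
      y[i, ] <- x[i, ] - (intercept + slope * ti)
    }
  }
  if (vec) y <- drop(y)
  list(y = y, state = state)
}

#' Causal moving-average low-pass smoothing
#'
#' Simple moving average over the last `window_len` samples, applied
#' `order` times in cascade (orders 1 to 5); at the start of the stream
#' the average runs over the samples seen so far (partial window), so a
#' constant passes through exactly from the first sample and the DC gain
#' is exactly 1.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param window_len window length in samples.
#' @param order number of cascaded passes, 1 to 5.
#' @return smoothed series, same shape as `x`.
#' @export
moving_average_lowpass <- function(x, window_len, order = 1L) {
  if (order < 1L || order > 5L) stop("order must be between 1 and 5")
  if (window_len < 1L) stop("window_len must be >= 1")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  for (pass in seq_len(order)) {
    cs <- apply(x, 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(x))
    lag <- rbind(
      matrix(0, min(window_len, n), ncol(x)),
      cs[seq_len(max(n - window_len, 0L)), , drop = FALSE]
    )
    x <- (cs - lag) / pmin(seq_len(n), window_len)
  }
  if (vec) x <- drop(x)
  x
}

#' Correlation-based motion correction (CBSI)
#'
#' Exploits the expected anti-correlation of HbO and Hb: with the
#' running scale ratio `alpha = sd(HbO) / sd(Hb)` (streaming moments
#' over all samples so far), the corrected signals are
#' `hbo' = (hbo - alpha * hb) / 2` and `hb' = -hbo' / alpha`, which
#' cancels common-mode artifacts (e.g. motion spikes that move HbO and
#' Hb in the same direction) and leaves the corrected pair exactly
#' anti-correlated. Strictly causal: the correction at `t` uses only
#' samples up to `t`. Until a channel has seen two distinct samples of
#' Hb, its data pass through uncorrected.
#'
#' @param hbo,hb numeric vectors or matrices (samples x channels).
#' @param state optional running-moment state from a previous call.
#' @return list with corrected `hbo`, `hb`, the final per-channel
#'   `alpha`, and `state`.
#' @export
motion_correct <- function(hbo, hb, state = NULL) {
  vec <- !is.matrix(hbo)
  if (vec) {
    hbo <- matrix(hbo, ncol = 1L)
    hb <- matrix(hb, ncol = 1L)
  }
  stopifnot(identical(dim(hbo), dim(hb)))
  nch <- ncol(hbo)
  if (is.null(state)) {
    state <- list(
      n = 0, s_o = numeric(nch), s_oo = numeric(nch),
      s_h = numeric(nch), s_hh = numeric(nch)
    )
  }
  out_o <- hbo
  out_h <- hb
  alpha_last <- rep(NA_real_, nch)
  for (i in seq_len(nrow(hbo))) {
    state$n <- state$n + 1
    state$s_o <- state$s_o + hbo[i, ]
    state$s_oo <- state$s_oo + hbo[i, ]^2
    state$s_h <- state$s_h + hb[i, ]
    state$s_hh <- state$s_hh + hb[i, ]^2
    n <- state$n
    if (n >= 2) {
      var_o <- (state$s_oo - state$s_o^2 / n) / (n - 1)
      var_h <- (state$s_hh - state$s_h^2 / n) / (n - 1)
      ok <- var_h > 0 & var_o > 0
      alpha <- sqrt(var_o / var_h)
      co <- (hbo[i, ] - alpha * hb[i, ]) / 2
      out_o[i, ok] <- co[ok]
      out_h[i, ok] <- (-co / alpha)[ok]
      alpha_last[ok] <- alpha[ok]
    }
  }
  if (vec) {
    out_o <- drop(out_o)
    out_h <- drop(out_h)
  }
  list(hbo = out_o, hb = out_h, alpha = alpha_last, state = state)
}

#' Sample-wise average of selected channels
#'
#' Builds the virtual "averaged channel" analyzed and plotted alongside
#' real channels.
#'
#' @param x matrix (samples x channels).
#' @param channels indices of the selected channels.
#' @return numeric vector of per-sample means.
#' @export
average_channels <- function(x, channels = seq_len(ncol(x))) {
  if (length(channels) < 1L) stop("at least one channel must be selected")
  rowMeans(x[, channels, drop = FALSE])
}
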