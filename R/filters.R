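#' Causal IIR/FIR filter specification
#'
#' Describes one filter of the streaming preprocessing bank. Supported
#' families: `"exponential-moving-average"`, `"simple-moving-average"`,
#' `"rbj-biquad"`, `"butterworth"`, `"chebyshev-1"`, `"chebyshev-2"`,
#' `"elliptic"`, `"bessel"`, `"legendre"` (optimum-monotonic, orders 1-5).
#' Kinds: `"low-pass"`, `"high-pass"`, `"band-pass"`, `"band-stop"`.
#' Band kinds take two cutoffs and are available for the biquad,
#' Butterworth, Chebyshev and elliptic families; Bessel and Legendre
#' support low- and high-pass only. For the moving-average families
#' `order` is the number of cascaded passes.
#'
#' @param family filter family (see above).
#' @param kind response kind.
#' @param order filter order (cascade count for EMA/SMA/RBJ).
#' @param cutoff_hz one cutoff, or `c(lo, hi)` for band kinds, in Hz.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param ripple_db passband ripple for Chebyshev-I/elliptic (dB).
#' @param stopband_db stopband attenuation for Chebyshev-II/elliptic (dB).
#' @param q resonance Q of the RBJ biquad (default `1/sqrt(2)`).
#' @param window_len window length in samples for the simple moving
#'   average; derived as `max(1, round(fs / (2 * cutoff)))` when omitted
#'   and a cutoff is given.
#' @return an object of class `"filter_spec"`.
#' @export
filter_spec <- function(family, kind = "low-pass", order = 2L, cutoff_hz = NULL,
                        sampling_rate_hz, ripple_db = 1, stopband_db = 40,
                        q = 1 / sqrt(2), window_len = NULL) {
  family <- match.arg(family, c(
    "exponential-moving-average", "simple-moving-average", "rbj-biquad",
    "butterworth", "chebyshev-1", "chebyshev-2", "elliptic",
    "bessel", "legendre"
  ))
  kind <- match.arg(kind, c("low-pass", "high-pass", "band-pass", "band-stop"))
  if (order < 1L) stop("order must be >= 1")
  band <- kind %in% c("band-pass", "band-stop")
  if (!is.null(cutoff_hz)) {
    if (band && length(cutoff_hz) != 2L) stop("band kinds need two cutoffs")
    if (!band && length(cutoff_hz) != 1L) stop("one cutoff expected")
    if (any(cutoff_hz <= 0) || any(cutoff_hz >= sampling_rate_hz / 2)) {
      stop("cutoffs must lie in (0, fs/2)")
    }
    if (band && cutoff_hz[1L] >= cutoff_hz[2L]) stop("need cutoff_lo < cutoff_hi")
  }
  structure(
    list(
      family = family, kind = kind, order = as.integer(order),
      cutoff_hz = cutoff_hz, sampling_rate_hz = sampling_rate_hz,
      ripple_db = ripple_db, stopband_db = stopband_db, q = q,
      window_len = window_len
    ),
    class = "filter_spec"
  )
}

# ---- analog prototype helpers (Bessel / Legendre) --------------------------

# reverse Bessel polynomial coefficients, ascending powers of s
reverse_bessel_poly <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

# poles of the analog Bessel low-pass prototype, scaled so |H(j*1)| = 1/sqrt(2)
bessel_prototype_poles <- function(n) {
  coefs <- reverse_bessel_poly(n)
  p <- polyroot(coefs) # delay-normalized poles
  magsq <- function(w) {
    s <- complex(real = 0, imaginary = w)
    num <- coefs[1L]
    den <- sum(coefs * s^(0:n))
    Mod(num / den)^2
  }
  w3 <- stats::uniroot(function(w) magsq(w) - 0.5, c(1e-6, 10 * n + 10),
                       tol = 1e-13)$root
  p / w3
}

# Papoulis optimum-L characteristic polynomials L_n(x), x = omega^2,
# ascending powers, orders 1..5; L_n(1) = 1 so the -3 dB point is exact.
legendre_L_table <- list(
  c(0, 1),
  c(0, 0, 1),
  c(0, 1, -3, 3),
  c(0, 0, 3, -8, 6),
  c(0, 1, -8, 28, -40, 20)
)

legendre_prototype_poles <- function(n) {
  if (n > 5L) stop("Legendre filters are supported up to order 5")
  Lc <- legendre_L_table[[n]]
  # 1 + L_n(-s^2): polynomial in s of degree 2n, ascending powers
  cs <- numeric(2 * n + 1)
  for (k in seq_along(Lc)) { # Lc[k] is the coefficient of x^(k-1)
    cs[2 * (k - 1) + 1] <- cs[2 * (k - 1) + 1] + Lc[k] * (-1)^(k - 1)
  }
  cs[1L] <- cs[1L] + 1
  r <- polyroot(cs)
  r[Re(r) < 0]
}

# bilinear transform of an analog zero/pole/gain filter; returns list(b, a)
zpk_bilinear <- function(zeros, poles, gain, fs) {
  f2 <- 2 * fs
  zd <- (f2 + zeros) / (f2 - zeros)
  pd <- (f2 + poles) / (f2 - poles)
  kd <- gain * prod(f2 - zeros) / prod(f2 - poles)
  # extra zeros at z = -1 to balance degrees
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# monic polynomial with the given roots, descending powers
poly_from_roots <- function(r) {
  cs <- 1 + 0i
  for (ri in r) cs <- c(cs, 0) - c(0, cs * ri)
  cs
}

# low-pass prototype (cutoff 1 rad/s, unit DC gain, all-pole) -> analog
# low- or high-pass at wc rad/s, as zero/pole/gain
analog_lp_transform <- function(poles, wc, kind) {
  gain0 <- Re(prod(-poles)) # unit DC gain for the prototype
  if (kind == "low-pass") {
    list(zeros = complex(0), poles = poles * wc, gain = gain0 * wc^length(poles))
  } else if (kind == "high-pass") {
    list(zeros = rep(0 + 0i, length(poles)), poles = wc / poles, gain = 1)
  } else {
    stop(sprintf("%s transformation is not supported for this family", kind))
  }
}

# RBJ audio-EQ cookbook biquad coefficients
rbj_biquad <- function(kind, f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  cf <- switch(kind,
    "low-pass" = list(b = c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)),
    "high-pass" = list(b = c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)),
    "band-pass" = list(b = c(alpha, 0, -alpha)),
    "band-stop" = list(b = c(1, -2 * cw, 1))
  )
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = cf$b / a[1L], a = a / a[1L])
}

# ---- design ----------------------------------------------------------------

#' Design a causal recursive filter
#'
#' Realizes a [filter_spec()] as one or more second-order-or-higher
#' sections with real coefficients, ready for strictly causal streaming
#' application with [apply_filter()]. The digital designs follow the
#' standard analog-prototype + bilinear-transform route; the design is
#' rejected if any pole lies on or outside the unit circle.
#'
#' @param spec a [filter_spec()].
#' @return an object of class `"nirs_filter"`: list of sections
#'   (`b`, `a` coefficient vectors) plus the spec.
#' @export
design_filter <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- spec$sampling_rate_hz
  fam <- spec$family
  kind <- spec$kind
  sections <- list()
  if (fam == "exponential-moving-average") {
    if (kind != "low-pass") stop("the EMA filter is low-pass only")
    if (is.null(spec$cutoff_hz)) stop("EMA needs a cutoff")
    alpha <- 1 - exp(-2 * pi * spec$cutoff_hz / fs)
    sec <- list(b = alpha, a = c(1, -(1 - alpha)))
    sections <- rep(list(sec), spec$order)
  } else if (fam == "simple-moving-average") {
    if (kind != "low-pass") stop("the moving-average filter is low-pass only")
    w <- spec$window_len
    if (is.null(w)) {
      if (is.null(spec$cutoff_hz)) stop("need window_len or cutoff_hz")
      w <- max(1L, round(fs / (2 * spec$cutoff_hz)))
    }
    sec <- list(b = rep(1 / w, w), a = 1)
    sections <- rep(list(sec), spec$order)
  } else if (fam == "rbj-biquad") {
    if (kind %in% c("band-pass", "band-stop")) {
      f0 <- sqrt(spec$cutoff_hz[1L] * spec$cutoff_hz[2L])
      qv <- f0 / (spec$cutoff_hz[2L] - spec$cutoff_hz[1L])
    } else {
      f0 <- spec$cutoff_hz
      qv <- spec$q
    }
    sections <- rep(list(rbj_biquad(kind, f0, fs, qv)), spec$order)
  } else if (fam %in% c("butterworth", "chebyshev-1", "chebyshev-2", "elliptic")) {
    W <- spec$cutoff_hz / (fs / 2)
    type <- switch(kind, "low-pass" = "low", "high-pass" = "high",
                   "band-pass" = "pass", "band-stop" = "stop")
    flt <- switch(fam,
      "butterworth" = signal::butter(spec$order, W, type = type),
      "chebyshev-1" = signal::cheby1(spec$order, spec$ripple_db, W, type = type),
      "chebyshev-2" = signal::cheby2(spec$order, spec$stopband_db, W, type = type),
      "elliptic" = signal::ellip(spec$order, spec$ripple_db, spec$stopband_db,
                                 W, type = type)
    )
    sections <- list(list(b = as.numeric(flt$b), a = as.numeric(flt$a)))
  } else { # bessel / legendre: analog prototype + bilinear transform
    if (kind %in% c("band-pass", "band-stop")) {
      stop(sprintf("%s transformation is not supported for the %s family",
                   kind, fam))
    }
    proto <- if (fam == "bessel") bessel_prototype_poles(spec$order)
             else legendre_prototype_poles(spec$order)
    wc <- 2 * fs * tan(pi * spec$cutoff_hz / fs) # prewarped
    zpk <- analog_lp_transform(proto, wc, kind)
    sections <- list(zpk_bilinear(zpk$zeros, zpk$poles, zpk$gain, fs))
  }
  for (sec in sections) {
    if (length(sec$a) > 1L) {
      poles <- polyroot(rev(sec$a))
      if (any(Mod(poles) >= 1 - 1e-12)) stop("unstable filter design")
    }
  }
  structure(list(sections = sections, spec = spec), class = "nirs_filter")
}

#' @export
print.nirs_filter <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "causal %s %s filter, order %d, cutoff %s Hz @ %g Hz (%d section%s)\n",
    s$family, s$kind, s$order,
    if (is.null(s$cutoff_hz)) "-" else paste(s$cutoff_hz, collapse = "-"),
    s$sampling_rate_hz, length(x$sections),
    if (length(x$sections) > 1L) "s" else ""
  ))
  invisible(x)
}

#' Initial (zero) streaming state of a filter
#'
#' @param filt a designed [design_filter()] object.
#' @param n_channels number of parallel channels the state will carry.
#' @return opaque state object for [apply_filter()].
#' @export
filter_init <- function(filt, n_channels = 1L) {
  lapply(filt$sections, function(sec) {
    n <- max(length(sec$b), length(sec$a))
    matrix(0, nrow = max(n - 1L, 1L), ncol = n_channels)
  })
}

#' Apply a causal filter to a stream
#'
#' Direct-form-II-transposed application, sample by sample, per channel.
#' Strictly causal with zero initial state: feeding a stream in chunks
#' (threading the returned state) yields bit-identical output to feeding
#' it at once, so the same code path serves offline and real-time use.
#'
#' @param filt a [design_filter()] result.
#' @param x numeric vector or matrix (samples x channels).
#' @param state previous state from [filter_init()] or an earlier call;
#'   zero state when `NULL`.
#' @return list with `y` (filtered, same shape as `x`) and `state`.
#' @export
apply_filter <- function(filt, x, state = NULL) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  if (is.null(state)) state <- filter_init(filt, ncol(x))
  y <- x
  for (si in seq_along(filt$sections)) {
    sec <- filt$sections[[si]]
    nmax <- max(length(sec$b), length(sec$a))
    b <- c(sec$b, rep(0, nmax - length(sec$b)))
    a <- c(sec$a, rep(0, nmax - length(sec$a)))
    z <- state[[si]]
    if (nmax == 1L) {
      y <- y * b[1L]
      next
    }
    out <- y
    for (t in seq_len(nrow(y))) {
      xt <- y[t, ]
      yt <- b[1L] * xt + z[1L, ]
      if (nmax > 2L) {
        for (k in seq_len(nmax - 2L)) {
          z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
        }
      }
      z[nmax - 1L, ] <- b[nmax] * xt - a[nmax] * yt
      out[t, ] <- yt
    }
    state[[si]] <- z
    y <- out
  }
  if (vec) y <- drop(y)
  list(y = y, state = state)
}

#' Filter a whole series (convenience wrapper)
#'
#' @inheritParams apply_filter
#' @return the filtered series only.
#' @export
filter_stream <- function(filt, x) apply_filter(filt, x)$y

#' Frequency response magnitude of a designed filter
#'
#' Evaluates `|H(f)|` of the realized difference equations directly
#' (product over cascaded sections of the ratio of trigonometric
#' polynomials), independent of any time-domain code path.
#'
#' @param filt a [design_filter()] result.
#' @param freq_hz frequencies at which to evaluate.
#' @return numeric vector of magnitudes.
#' @export
filter_response <- function(filt, freq_hz) {
  w <- 2 * pi * freq_hz / filt$spec$sampling_rate_hz
  H <- rep(1 + 0i, length(w))
  for (sec in filt$sections) {
    num <- vapply(w, function(wi) {
      sum(sec$b * exp(-1i * wi * (seq_along(sec$b) - 1L)))
    }, complex(1))
    den <- vapply(w, function(wi) {
      sum(sec$a * exp(-1i * wi * (seq_along(sec$a) - 1L)))
    }, complex(1))
    H <- H * num / den
  }
  Mod(H)
}

#' Magnitude spectrum of the most recent window
#'
#' Discrete Fourier magnitude of a signal window, reported for
#' frequencies up to 1.4 Hz (or Nyquist, whichever is lower) — the live
#' spectrogram used to judge filter settings.
#'
#' @param x numeric vector (the most recent window of one channel).
#' @param fs sampling rate in Hz.
#' @param fmax_hz upper frequency bound of the report (default 1.4).
#' @return data.frame with `freq_hz` and `magnitude` (amplitude units of
#'   `x`; single-sided scaling).
#' @export
magnitude_spectrum <- function(x, fs, fmax_hz = 1.4) {
  n <- length(x)
  if (n < 2L) stop("window length must be >= 2")
  X <- stats::fft(x)
  nyq <- fs / 2
  kmax <- floor(min(fmax_hz, nyq) * n / fs)
  k <- 0:min(kmax, floor(n / 2))
  mag <- Mod(X[k + 1L]) / n
  mag[k > 0] <- 2 * mag[k > 0]
  data.frame(freq_hz = k * fs / n, magnitude = mag)
}
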