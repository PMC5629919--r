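#' Synthetic fNIRS session specification
#'
#' Describes a forward simulation: ground-truth hemodynamic responses
#' (HRF-convolved condition boxcars scaled by a per-condition,
#' per-channel amplitude map), physiological noise, and the
#' Beer-Lambert forward model that turns concentrations into raw
#' two-wavelength intensities.
#'
#' Noise model per channel: white Gaussian noise, a linear drift, and
#' sinusoidal physiological oscillations (cardiac ~1.0 Hz, respiratory
#' ~0.3 Hz, Mayer waves ~0.1 Hz) with random phase per channel, plus
#' optional common-mode motion spikes added with the same sign to HbO
#' and Hb (the artifact geometry the correlation-based motion
#' correction assumes). The Hb ground truth defaults to `-1/3` of the
#' HbO response, the typical inverse deflection.
#'
#' @param montage a [montage()].
#' @param protocol a [protocol()].
#' @param amplitude matrix (conditions x channels) of response
#'   amplitudes, mmol/l of HbO at the response peak.
#' @param hb_ratio Hb response as a fraction of the HbO response.
#' @param hrf_params HRF overrides, see [hrf_double_gamma()].
#' @param white_sd white noise standard deviation, mmol/l.
#' @param drift_slope linear drift, mmol/l per second.
#' @param osc_freq_hz,osc_amp oscillation frequencies (Hz) and
#'   amplitudes (mmol/l), parallel vectors.
#' @param spike_rate_hz expected motion-spike rate (0 disables).
#' @param spike_amp spike amplitude, mmol/l.
#' @param I0 baseline raw intensity per wavelength (recycled across
#'   channels).
#' @param seed RNG seed; fixed seed gives bit-reproducible sessions.
#' @return an object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(montage, protocol, amplitude,
                            hb_ratio = -1 / 3, hrf_params = list(),
                            white_sd = 5e-4, drift_slope = 1e-6,
                            osc_freq_hz = c(1.0, 0.3, 0.1),
                            osc_amp = c(1e-4, 1e-4, 1e-4),
                            spike_rate_hz = 0, spike_amp = 5e-3,
                            I0 = c(1.0, 1.0), seed = 1L) {
  amplitude <- as.matrix(amplitude)
  if (ncol(amplitude) != n_channels(montage)) {
    stop("amplitude map must have one column per channel")
  }
  if (nrow(amplitude) != length(protocol$conditions)) {
    stop("amplitude map must have one row per condition")
  }
  if (any(!is.finite(amplitude))) stop("amplitudes must be finite")
  if (any(I0 <= 0)) stop("baseline intensities must be > 0")
  structure(
    list(
      montage = montage, protocol = protocol, amplitude = amplitude,
      hb_ratio = hb_ratio, hrf_params = hrf_params, white_sd = white_sd,
      drift_slope = drift_slope, osc_freq_hz = osc_freq_hz,
      osc_amp = osc_amp, spike_rate_hz = spike_rate_hz,
      spike_amp = spike_amp, I0 = I0, seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Simulate ground-truth and noisy concentration series
#'
#' @param spec a [simulation_spec()].
#' @return list with matrices `hbo`, `hb` (noisy, samples x channels),
#'   `clean_hbo`, `clean_hb`, the `amplitude` truth map, and
#'   `spike_samples` (list of spike positions per channel).
#' @export
simulate_concentration <- function(spec) {
  set.seed(spec$seed)
  prot <- spec$protocol
  fs <- prot$sampling_rate_hz
  n <- protocol_n_samples(prot)
  nch <- n_channels(spec$montage)
  conds <- names(prot$conditions)
  clean <- matrix(0, n, nch)
  for (ci in seq_along(conds)) {
    pred <- convolve_boxcar_hrf(condition_mask(prot, conds[ci], n), fs,
                                spec$hrf_params)
    clean <- clean + outer(pred, spec$amplitude[ci, ])
  }
  clean_hb <- spec$hb_ratio * clean
  t_s <- (seq_len(n) - 1L) / fs
  hbo <- clean
  hb <- clean_hb
  spike_samples <- vector("list", nch)
  for (ch in seq_len(nch)) {
    osc_o <- osc_d <- 0
    for (k in seq_along(spec$osc_freq_hz)) {
      osc_o <- osc_o + spec$osc_amp[k] *
        sin(2 * pi * spec$osc_freq_hz[k] * t_s + stats::runif(1, 0, 2 * pi))
      osc_d <- osc_d + abs(spec$hb_ratio) * spec$osc_amp[k] *
        sin(2 * pi * spec$osc_freq_hz[k] * t_s + stats::runif(1, 0, 2 * pi))
    }
    hbo[, ch] <- hbo[, ch] + osc_o + spec$drift_slope * t_s +
      stats::rnorm(n, sd = spec$white_sd)
    hb[, ch] <- hb[, ch] + osc_d + spec$hb_ratio * spec$drift_slope * t_s +
      stats::rnorm(n, sd = abs(spec$hb_ratio) * spec$white_sd)
    if (spec$spike_rate_hz > 0) {
      n_spikes <- stats::rpois(1, spec$spike_rate_hz * n / fs)
      if (n_spikes > 0) {
        at <- sample.int(n, n_spikes)
        sgn <- sample(c(-1, 1), n_spikes, replace = TRUE)
        # common-mode: same sign and size on both chromophores
        hbo[at, ch] <- hbo[at, ch] + sgn * spec$spike_amp
        hb[at, ch] <- hb[at, ch] + sgn * spec$spike_amp
        spike_samples[[ch]] <- sort(at)
      }
    }
  }
  list(hbo = hbo, hb = hb, clean_hbo = clean, clean_hb = clean_hb,
       amplitude = spec$amplitude, spike_samples = spike_samples)
}

#' Forward-model concentrations to raw intensities
#'
#' Inverse of the streaming MBLL conversion:
#' `I_l(t) = I0_l * 10^(-d * DPF_l * (eps_hbo_l * dHbO + eps_hb_l * dHb))`
#' per channel and wavelength, so converting the result back through
#' [stream_convert()] (with a baseline window in which the
#' concentrations are zero) recovers the concentration series.
#'
#' @param conc list with matrices `hbo` and `hb` (samples x channels),
#'   mmol/l.
#' @param spec a [simulation_spec()] (supplies montage distances and
#'   baseline intensities).
#' @param ext an [extinction_table()].
#' @return list with intensity matrices `wl1`, `wl2`.
#' @export
to_raw_intensities <- function(conc, spec, ext = extinction_table()) {
  d <- spec$montage$distance_cm
  nch <- n_channels(spec$montage)
  mk <- function(lam) {
    att <- sweep(
      conc$hbo * ext$E[lam, 1L] + conc$hb * ext$E[lam, 2L],
      2L, d * ext$dpf[lam], "*"
    )
    spec$I0[lam] * 10^(-att)
  }
  list(wl1 = mk(1L), wl2 = mk(2L))
}

#' Lateralized finger-tapping montage (20 channels)
#'
#' An 8-source, 8-detector montage with 20 channels in source-major
#' order; channels 1-10 (sources 2-6) lie over the left hemisphere and
#' channels 11-20 (sources 12-16) over the right, so channel #1 is
#' source 2 / detector 1.
#'
#' @param distance_cm source-detector separation, cm.
#' @return a [montage()].
#' @export
finger_tapping_montage <- function(distance_cm = 3.0) {
  left <- rbind(
    c(2, 1), c(2, 2), c(3, 1), c(3, 2), c(3, 4),
    c(4, 2), c(4, 4), c(4, 5), c(6, 4), c(6, 5)
  )
  right <- rbind(
    c(12, 11), c(12, 14), c(13, 11), c(13, 14), c(13, 15),
    c(14, 14), c(14, 15), c(14, 16), c(16, 15), c(16, 16)
  )
  montage(rbind(left, right), distance_cm = distance_cm)
}

#' Simulated lateralized finger-tapping session
#'
#' Generates the canonical in-silico decoding benchmark: three runs
#' (two training, one test) of a two-condition blocked left/right
#' finger-tapping protocol at 7.8125 Hz over the 20-channel
#' [finger_tapping_montage()]. Responses are contralateral: the
#' `"left"` condition drives channels 11-20 (right hemisphere) and
#' `"right"` drives channels 1-10. Each run has 12 trials per
#' condition (10 s task, 20 s rest, alternating), after a 30 s lead-in
#' rest that accommodates the streaming baseline window.
#'
#' @param seed RNG seed; each run r uses `seed + r - 1`.
#' @param n_runs number of runs (default 3).
#' @param trials_per_condition trials per condition per run (default 12).
#' @param amplitude_mmol peak HbO response amplitude on driven channels.
#' @param fs sampling rate in Hz.
#' @param task_s,rest_s block and inter-block durations, seconds.
#' @param lead_in_s initial rest before the first block, seconds.
#' @param ... further overrides passed to [simulation_spec()].
#' @return list with `montage`, `runs` (each: `protocol`, `conc` truth
#'   list, `raw` intensity matrices, `sim_spec`), and the `amplitude`
#'   truth map.
#' @export
make_finger_tapping_session <- function(seed = 1L, n_runs = 3L,
                                        trials_per_condition = 12L,
                                        amplitude_mmol = 1e-3,
                                        fs = 7.8125, task_s = 10,
                                        rest_s = 20, lead_in_s = 30, ...) {
  mont <- finger_tapping_montage()
  n_trials <- 2L * trials_per_condition
  onsets <- lead_in_s + (seq_len(n_trials) - 1L) * (task_s + rest_s)
  total <- lead_in_s + n_trials * (task_s + rest_s)
  left_iv <- cbind(onsets[seq(1L, n_trials, by = 2L)],
                   onsets[seq(1L, n_trials, by = 2L)] + task_s)
  right_iv <- cbind(onsets[seq(2L, n_trials, by = 2L)],
                    onsets[seq(2L, n_trials, by = 2L)] + task_s)
  prot <- protocol(fs, list(left = left_iv, right = right_iv), total)
  amp <- rbind(
    left = c(rep(0, 10), rep(amplitude_mmol, 10)), # contralateral
    right = c(rep(amplitude_mmol, 10), rep(0, 10))
  )
  runs <- lapply(seq_len(n_runs), function(r) {
    sspec <- simulation_spec(mont, prot, amp, seed = seed + r - 1L, ...)
    conc <- simulate_concentration(sspec)
    list(protocol = prot, conc = conc,
         raw = to_raw_intensities(conc, sspec), sim_spec = sspec)
  })
  list(montage = mont, runs = runs, amplitude = amp)
}
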