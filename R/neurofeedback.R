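#' Neurofeedback settings
#'
#' Configures how the thermometer feedback value is computed from the
#' preprocessed concentration signal of the selected channels. Feedback
#' is the deviation of the current channel-averaged signal from the most
#' recent baseline level; deoxygenated hemoglobin is inverted so a
#' negative Hb deflection gives positive feedback. The baseline window
#' is shifted into the block to respect hemodynamic delay: it starts
#' `shift_at_begin_s` seconds after baseline-block onset (protects
#' against the decaying response of the previous modulation) and ends
#' `shift_at_end_s` seconds after baseline-block offset (the response of
#' the new modulation block only rises after 2-3 s). Shifted windows
#' shorter than `min_baseline_s` (hard minimum 4 s; at least 10 s is
#' recommended) are invalid and suppress feedback output.
#'
#' @param source `"oxy"`, `"deoxy"`, or `"combined"`.
#' @param channels indices of the channels averaged for feedback.
#' @param shift_at_begin_s baseline start shift, seconds (default 5).
#' @param shift_at_end_s baseline end shift, seconds (default 1).
#' @param max_val_oxy,max_val_deoxy feedback value mapped to a full
#'   thermometer, in the units of the preprocessed signal.
#' @param thermometer_levels number of thermometer rectangles (default 10).
#' @param min_baseline_s minimum valid baseline duration, seconds.
#' @return an object of class `"feedback_spec"`.
#' @export
feedback_spec <- function(source = c("oxy", "deoxy", "combined"),
                          channels = 1L, shift_at_begin_s = 5,
                          shift_at_end_s = 1, max_val_oxy = 1,
                          max_val_deoxy = 1, thermometer_levels = 10L,
                          min_baseline_s = 4) {
  if (shift_at_begin_s < 0 || shift_at_end_s < 0) stop("shifts must be >= 0")
  if (max_val_oxy <= 0 || max_val_deoxy <= 0) stop("max values must be > 0")
  if (thermometer_levels < 1L) stop("need at least one thermometer level")
  if (min_baseline_s < 4) stop("the minimum baseline duration is 4 s")
  structure(
    list(
      source = match.arg(source), channels = channels,
      shift_at_begin_s = shift_at_begin_s, shift_at_end_s = shift_at_end_s,
      max_val_oxy = max_val_oxy, max_val_deoxy = max_val_deoxy,
      thermometer_levels = as.integer(thermometer_levels),
      min_baseline_s = min_baseline_s
    ),
    class = "feedback_spec"
  )
}

#' Hemodynamically shifted baseline interval
#'
#' Shifts a baseline block `[b0, b1)` to
#' `[b0 + shift_at_begin_s, b1 + shift_at_end_s)`; e.g. a block from 50
#' to 70 s with shifts 5 and 1 s yields the effective interval 55 to
#' 71 s (16 s). Intervals shorter than the minimum baseline duration
#' are invalid.
#'
#' @param block length-2 vector `c(onset_s, offset_s)` of the baseline
#'   block.
#' @param spec a [feedback_spec()].
#' @return list with `interval` (`c(start_s, end_s)`), `duration_s`, and
#'   logical `valid`.
#' @export
effective_baseline_interval <- function(block, spec = feedback_spec()) {
  if (block[2L] <= block[1L]) stop("baseline block must have onset < offset")
  iv <- c(block[1L] + spec$shift_at_begin_s, block[2L] + spec$shift_at_end_s)
  dur <- iv[2L] - iv[1L]
  list(interval = iv, duration_s = dur, valid = dur >= spec$min_baseline_s)
}

#' Baseline level over an interval
#'
#' Arithmetic mean of the channel-averaged HbO and Hb signals over the
#' (already shifted) baseline interval.
#'
#' @param hbo,hb matrices (samples x channels) of the preprocessed
#'   concentration signal.
#' @param interval result of [effective_baseline_interval()].
#' @param fs sampling rate in Hz.
#' @param spec a [feedback_spec()] (selects and averages channels).
#' @return list with `oxy_bl`, `deoxy_bl`, `n_samples`, `interval`, and
#'   `valid`; invalid intervals yield no level (`valid = FALSE`).
#' @export
compute_baseline_level <- function(hbo, hb, interval, fs,
                                   spec = feedback_spec()) {
  if (!interval$valid) {
    return(list(oxy_bl = NA_real_, deoxy_bl = NA_real_, n_samples = 0L,
                interval = interval$interval, valid = FALSE))
  }
  if (length(spec$channels) < 1L) stop("empty channel selection")
  i0 <- floor(interval$interval[1L] * fs)
  i1 <- floor(interval$interval[2L] * fs) - 1L
  i1 <- min(i1, nrow(as.matrix(hbo)) - 1L)
  if (i1 < i0) {
    return(list(oxy_bl = NA_real_, deoxy_bl = NA_real_, n_samples = 0L,
                interval = interval$interval, valid = FALSE))
  }
  idx <- seq.int(i0 + 1L, i1 + 1L)
  o <- average_channels(as.matrix(hbo), spec$channels)[idx]
  d <- average_channels(as.matrix(hb), spec$channels)[idx]
  list(oxy_bl = mean(o), deoxy_bl = mean(d), n_samples = length(idx),
       interval = interval$interval, valid = TRUE)
}

#' Feedback value relative to a baseline level
#'
#' `fb_oxy = oxy - oxy_bl`; `fb_deoxy = -(deoxy - deoxy_bl)` (inverted
#' so a negative Hb deflection is positive feedback);
#' `fb_combined = ((oxy - oxy_bl) - (deoxy - deoxy_bl)) / 2`, the mean
#' of the two.
#'
#' @param oxy,deoxy current channel-averaged signal values.
#' @param level a valid [compute_baseline_level()] result.
#' @param spec a [feedback_spec()]; selects which value is returned in
#'   `fb`.
#' @return list with `fb` (selected source), `fb_oxy`, `fb_deoxy`,
#'   `fb_combined`.
#' @export
feedback_value <- function(oxy, deoxy, level, spec = feedback_spec()) {
  if (!isTRUE(level$valid)) stop("no valid baseline level; feedback suppressed")
  fb_oxy <- oxy - level$oxy_bl
  fb_deoxy <- -1 * (deoxy - level$deoxy_bl)
  fb_combined <- ((oxy - level$oxy_bl) - (deoxy - level$deoxy_bl)) / 2
  fb <- switch(spec$source, oxy = fb_oxy, deoxy = fb_deoxy,
               combined = fb_combined)
  list(fb = fb, fb_oxy = fb_oxy, fb_deoxy = fb_deoxy,
       fb_combined = fb_combined)
}

#' Thermometer fill level
#'
#' Maps a feedback value to the number of filled thermometer rectangles:
#' the fill fraction `fb / max_val` is clamped to `[0, 1]` and rounded
#' half away from zero to an integer level, e.g. `fb = 0.25` with
#' `max_val = 0.5` fills 5 of 10 rectangles.
#'
#' @param fb feedback value.
#' @param max_val feedback value corresponding to a full thermometer.
#' @param levels number of rectangles (default 10).
#' @return integer in `0..levels`.
#' @export
thermometer_level <- function(fb, max_val, levels = 10L) {
  if (max_val <= 0) stop("max_val must be > 0")
  if (levels < 1L) stop("levels must be >= 1")
  frac <- pmin(pmax(fb / max_val, 0), 1)
  as.integer(floor(frac * levels + 0.5))
}

#' Run a neurofeedback session over a recorded or simulated stream
#'
#' Walks the protocol's alternating baseline / modulation blocks. For
#' each modulation block the most recent valid (shifted) baseline level
#' is used; one record is emitted per sample of the modulation block
#' from the moment that level is complete (the end-shift extends the
#' baseline into the modulation block, so its first `shift_at_end_s`
#' seconds cannot produce output — causality is never violated). With
#' no valid baseline, output for the block is suppressed.
#'
#' @param hbo,hb matrices (samples x channels) of the preprocessed
#'   concentration signal.
#' @param protocol a [protocol()] containing the two conditions.
#' @param spec a [feedback_spec()].
#' @param baseline_condition,modulation_condition condition names.
#' @return data.frame with `t_s`, `fb_oxy`, `fb_deoxy`, `fb_combined`,
#'   `fb`, `level` (one row per emitted sample).
#' @export
run_feedback_session <- function(hbo, hb, protocol, spec = feedback_spec(),
                                 baseline_condition = "baseline",
                                 modulation_condition = "modulation") {
  if (!baseline_condition %in% names(protocol$conditions)) {
    warning("protocol has no baseline condition; no feedback produced")
    return(data.frame(t_s = numeric(0), fb_oxy = numeric(0),
                      fb_deoxy = numeric(0), fb_combined = numeric(0),
                      fb = numeric(0), level = integer(0)))
  }
  fs <- protocol$sampling_rate_hz
  hbo <- as.matrix(hbo)
  hb <- as.matrix(hb)
  bl_blocks <- condition_trials(protocol, baseline_condition)
  mod_blocks <- condition_trials(protocol, modulation_condition)
  o_avg <- average_channels(hbo, spec$channels)
  d_avg <- average_channels(hb, spec$channels)
  max_val <- switch(spec$source, oxy = spec$max_val_oxy,
                    deoxy = spec$max_val_deoxy,
                    combined = (spec$max_val_oxy + spec$max_val_deoxy) / 2)
  rows <- list()
  for (k in seq_len(nrow(mod_blocks))) {
    m0 <- mod_blocks[k, 1L]
    m1 <- mod_blocks[k, 2L]
    prev <- bl_blocks[bl_blocks[, 2L] <= m0 + 1e-9, , drop = FALSE]
    if (!nrow(prev)) next
    iv <- effective_baseline_interval(prev[nrow(prev), ], spec)
    if (!iv$valid) next
    level_bl <- compute_baseline_level(hbo, hb, iv, fs, spec)
    if (!level_bl$valid) next
    # emit from the later of block start and baseline completion
    s0 <- max(floor(m0 * fs), floor(iv$interval[2L] * fs))
    s1 <- min(floor(m1 * fs) - 1L, nrow(hbo) - 1L)
    if (s1 < s0) next
    for (s in s0:s1) {
      fb <- feedback_value(o_avg[s + 1L], d_avg[s + 1L], level_bl, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        t_s = s / fs, fb_oxy = fb$fb_oxy, fb_deoxy = fb$fb_deoxy,
        fb_combined = fb$fb_combined, fb = fb$fb,
        level = thermometer_level(fb$fb, max_val, spec$thermometer_levels)
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(t_s = numeric(0), fb_oxy = numeric(0),
                      fb_deoxy = numeric(0), fb_combined = numeric(0),
                      fb = numeric(0), level = integer(0)))
  }
  do.call(rbind, rows)
}
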