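#' Extinction coefficients and differential path length factors
#'
#' Constants used by the modified Beer-Lambert law (MBLL) to convert
#' optical-density changes at two wavelengths into hemoglobin
#' concentration changes. The defaults are the adult-head values for the
#' standard 760/850 nm wavelength pair: differential path length factors
#' (DPF) 6.40 and 5.75, and molar extinction coefficients, in
#' l/(cm*mmol), of 1.4865865 (HbO) and 3.843707 (Hb) at 760 nm, and
#' 2.526391 (HbO) and 1.798643 (Hb) at 850 nm.
#'
#' @param wavelengths_nm the two wavelengths.
#' @param dpf per-wavelength differential path length factor (unitless).
#' @param eps_hbo,eps_hb per-wavelength molar extinction coefficients for
#'   oxygenated / deoxygenated hemoglobin, l/(cm*mmol).
#' @return an object of class `"extinction_table"` with the 2x2 extinction
#'   matrix `E` (rows = wavelengths, columns = HbO, Hb).
#' @export
extinction_table <- function(wavelengths_nm = c(760, 850),
                             dpf = c(6.40, 5.75),
                             eps_hbo = c(1.4865865, 2.526391),
                             eps_hb = c(3.843707, 1.798643)) {
  stopifnot(length(dpf) == 2L, length(eps_hbo) == 2L, length(eps_hb) == 2L)
  if (any(c(dpf, eps_hbo, eps_hb) <= 0)) stop("all MBLL parameters must be > 0")
  E <- cbind(hbo = eps_hbo, hb = eps_hb)
  rownames(E) <- paste0("nm", wavelengths_nm)
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  structure(
    list(wavelengths_nm = wavelengths_nm, dpf = dpf, E = E),
    class = "extinction_table"
  )
}

#' Baseline raw intensity
#'
#' Arithmetic mean raw intensity per channel and wavelength over the
#' configured baseline window (by default the first 200 received samples).
#' Channels whose mean intensity is zero at either wavelength are flagged
#' invalid and excluded downstream rather than raising an error, so that a
#' running acquisition is not halted by a dead channel.
#'
#' @param raw list with matrices `wl1` and `wl2` (samples x channels) of
#'   raw intensities at the two wavelengths.
#' @param config a [recording_config()].
#' @return an object of class `"baseline_intensity"`: matrices `I0_wl1`,
#'   `I0_wl2` (1 x channels), logical `valid` per channel, and the window.
#' @export
compute_baseline <- function(raw, config = recording_config()) {
  check_raw(raw)
  n <- nrow(raw$wl1)
  if (n < config$hb_baseline_end) {
    stop(sprintf(
      "need %d samples for the baseline window, have %d",
      config$hb_baseline_end, n
    ))
  }
  idx <- seq.int(config$hb_baseline_begin + 1L, config$hb_baseline_end)
  I0_wl1 <- colMeans(raw$wl1[idx, , drop = FALSE])
  I0_wl2 <- colMeans(raw$wl2[idx, , drop = FALSE])
  structure(
    list(
      I0_wl1 = I0_wl1, I0_wl2 = I0_wl2,
      valid = I0_wl1 > 0 & I0_wl2 > 0,
      window = c(begin = config$hb_baseline_begin, end = config$hb_baseline_end)
    ),
    class = "baseline_intensity"
  )
}

check_raw <- function(raw) {
  if (!is.list(raw) || is.null(raw$wl1) || is.null(raw$wl2)) {
    stop("raw data must be a list with matrices `wl1` and `wl2`")
  }
  if (!identical(dim(raw$wl1), dim(raw$wl2))) {
    stop("wl1 and wl2 matrices must have identical dimensions")
  }
  invisible(raw)
}

#' Optical density change
#'
#' `dOD = -log10(I / I0)`: attenuation of the detected intensity relative
#' to its baseline. Nonpositive intensities yield `NA` (the sample is
#' flagged missing, not an error, so streaming continues).
#'
#' @param I current intensity (vector or matrix).
#' @param I0 baseline intensity, recycled against `I`.
#' @return unitless optical-density change, same shape as `I`.
#' @export
to_optical_density <- function(I, I0) {
  bad <- !is.finite(I) | !is.finite(I0) | I <= 0 | I0 <= 0
  out <- suppressWarnings(-log10(I / I0)) # invalid samples become NA below
  out[bad | !is.finite(out)] <- NA_real_
  out
}

#' Concentration change from optical densities
#'
#' Solves the MBLL 2x2 linear system. With optical-density changes
#' `dOD_l` at the two wavelengths, path length `distance_cm * DPF_l`, and
#' extinction matrix `E` (rows = wavelengths, columns = HbO / Hb):
#' `dOD_l / (distance_cm * DPF_l) = E %*% c(dHbO, dHb)`. Concentrations
#' are in mmol/l given coefficients in l/(cm*mmol) and distances in cm.
#'
#' @param dod length-2 vector, or 2-column matrix (rows = observations),
#'   of optical-density changes at the two wavelengths.
#' @param ext an [extinction_table()].
#' @param distance_cm source-detector separation in cm.
#' @return named vector `c(hbo, hb)`, or a 2-column matrix for matrix input.
#' @export
to_concentration <- function(dod, ext = extinction_table(), distance_cm = 3.0) {
  if (distance_cm <= 0) stop("distance_cm must be > 0")
  Einv <- solve(ext$E)
  if (is.matrix(dod)) {
    scaled <- sweep(dod, 2L, distance_cm * ext$dpf, "/")
    out <- scaled %*% t(Einv)
    colnames(out) <- c("hbo", "hb")
    out
  } else {
    v <- drop(Einv %*% (dod / (distance_cm * ext$dpf)))
    names(v) <- c("hbo", "hb")
    v
  }
}

#' Streaming MBLL conversion
#'
#' Converts a stream of raw two-wavelength frames to HbO/Hb concentration
#' changes. Nothing is emitted before the baseline window completes; once
#' it does, the frames of the baseline period are converted retroactively
#' and every subsequent frame is converted as it arrives, so offline
#' reanalysis of a recording reproduces the online output exactly.
#'
#' @param raw list with matrices `wl1`, `wl2` (samples x channels).
#' @param config a [recording_config()].
#' @param ext an [extinction_table()].
#' @param montage optional [montage()]; supplies per-channel
#'   source-detector distances (default 3 cm without one).
#' @param baseline optional precomputed [compute_baseline()] result (e.g.
#'   known true baseline intensities); computed from the configured
#'   window when `NULL`.
#' @return list of class `"concentration_series"`: matrices `hbo`, `hb`
#'   (samples x channels, mmol/l; `NA` rows before baseline completion and
#'   `NA` columns for invalid channels), logical `valid` per channel, and
#'   `baseline`.
#' @export
stream_convert <- function(raw, config = recording_config(),
                           ext = extinction_table(), montage = NULL,
                           baseline = NULL) {
  check_raw(raw)
  n <- nrow(raw$wl1)
  nch <- ncol(raw$wl1)
  dist <- if (is.null(montage)) rep(3.0, nch) else {
    if (n_channels(montage) != nch) stop("montage channel count does not match raw data")
    montage$distance_cm
  }
  if (is.null(baseline)) baseline <- compute_baseline(raw, config)
  hbo <- matrix(NA_real_, n, nch)
  hb <- matrix(NA_real_, n, nch)
  Einv <- solve(ext$E)
  for (ci in seq_len(nch)) {
    if (!baseline$valid[ci]) next
    dod1 <- to_optical_density(raw$wl1[, ci], baseline$I0_wl1[ci])
    dod2 <- to_optical_density(raw$wl2[, ci], baseline$I0_wl2[ci])
    s1 <- dod1 / (dist[ci] * ext$dpf[1L])
    s2 <- dod2 / (dist[ci] * ext$dpf[2L])
    hbo[, ci] <- Einv[1L, 1L] * s1 + Einv[1L, 2L] * s2
    hb[, ci] <- Einv[2L, 1L] * s1 + Einv[2L, 2L] * s2
  }
  structure(
    list(hbo = hbo, hb = hb, valid = baseline$valid, baseline = baseline,
         first_emitted = config$hb_baseline_end),
    class = "concentration_series"
  )
}

#' Read / write raw two-wavelength intensity matrices
#'
#' The on-disk convention mirrors NIRx `.wl1`/`.wl2` files: one
#' whitespace-separated numeric matrix per wavelength, one row per scan
#' frame, one column per channel. A truncated final line is dropped.
#'
#' @param path_wl1,path_wl2 file paths for the two wavelengths.
#' @return `read_raw_wl()` returns a list with matrices `wl1`, `wl2`.
#' @export
read_raw_wl <- function(path_wl1, path_wl2) {
  rd <- function(p) {
    rows <- strsplit(trimws(readLines(p, warn = FALSE)), "[ \t]+")
    rows <- rows[vapply(rows, function(r) length(r) > 0L && any(r != ""), logical(1))]
    if (!length(rows)) stop(sprintf("%s: empty raw matrix", p))
    width <- length(rows[[1L]])
    keep <- vapply(rows, length, integer(1)) == width
    do.call(rbind, lapply(rows[keep], as.numeric))
  }
  w1 <- rd(path_wl1)
  w2 <- rd(path_wl2)
  n <- min(nrow(w1), nrow(w2)) # a truncated file ends the stream cleanly
  out <- list(wl1 = w1[seq_len(n), , drop = FALSE],
              wl2 = w2[seq_len(n), , drop = FALSE])
  check_raw(out)
  out
}

#' @rdname read_raw_wl
#' @param raw list with matrices `wl1`, `wl2`.
#' @export
write_raw_wl <- function(raw, path_wl1, path_wl2) {
  check_raw(raw)
  wr <- function(m, p) {
    writeLines(apply(format(m, trim = TRUE, digits = 15), 1L, paste, collapse = " "), p)
  }
  wr(raw$wl1, path_wl1)
  wr(raw$wl2, path_wl2)
  invisible(c(path_wl1, path_wl2))
}

#' Write a concentration series as long-format CSV
#'
#' Columns: `time_s`, `channel`, `hbo`, `hb`.
#'
#' @param conc a `"concentration_series"` (or any list with `hbo`/`hb`
#'   matrices).
#' @param path output path.
#' @param sampling_rate_hz sampling rate used for the `time_s` column.
#' @export
write_concentration_csv <- function(conc, path, sampling_rate_hz) {
  n <- nrow(conc$hbo)
  nch <- ncol(conc$hbo)
  df <- data.frame(
    time_s = rep((seq_len(n) - 1L) / sampling_rate_hz, times = nch),
    channel = rep(seq_len(nch), each = n),
    hbo = as.vector(conc$hbo),
    hb = as.vector(conc$hb)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
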