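#' Stimulation protocol
#'
#' A protocol names the experimental conditions and their block intervals.
#' Intervals are in seconds and half-open: a block `[onset, offset)`
#' contains sample `i` (0-based) iff `onset <= i / sampling_rate < offset`.
#'
#' @param sampling_rate_hz acquisition sampling rate in Hz.
#' @param conditions named list; each element is a two-column matrix (or
#'   anything coercible) of `[onset, offset)` intervals in seconds.
#' @param total_duration_s total recording duration in seconds.
#' @return an object of class `"nirs_protocol"`.
#' @examples
#' p <- protocol(1, list(task = rbind(c(50, 70))), total_duration_s = 100)
#' sum(condition_mask(p, "task", n_samples = 100))
#' @export
protocol <- function(sampling_rate_hz, conditions, total_duration_s) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0")
  }
  if (length(conditions) &&
      (is.null(names(conditions)) || any(names(conditions) == ""))) {
    stop("conditions must be a named list")
  }
  if (anyDuplicated(names(conditions))) stop("duplicate condition names")
  conditions <- lapply(conditions, function(iv) {
    iv <- matrix(as.numeric(iv), ncol = 2L,
                 dimnames = list(NULL, c("onset", "offset")))
    if (nrow(iv) == 0L) return(iv)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] >= iv[, 2L])) stop("interval with onset >= offset")
    if (any(iv[, 1L] < 0) || any(iv[, 2L] > total_duration_s + 1e-9)) {
      stop("interval outside [0, total_duration_s]")
    }
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
      stop("overlapping intervals within a condition")
    }
    iv
  })
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      conditions = conditions,
      total_duration_s = total_duration_s
    ),
    class = "nirs_protocol"
  )
}

#' @export
print.nirs_protocol <- function(x, ...) {
  cat(sprintf(
    "fNIRS protocol: %g Hz, %g s, %d condition(s)\n",
    x$sampling_rate_hz, x$total_duration_s, length(x$conditions)
  ))
  for (nm in names(x$conditions)) {
    cat(sprintf("  %s: %d block(s)\n", nm, nrow(x$conditions[[nm]])))
  }
  invisible(x)
}

#' Number of samples covered by a protocol
#' @param protocol a [protocol()] object.
#' @export
protocol_n_samples <- function(protocol) {
  as.integer(floor(protocol$total_duration_s * protocol$sampling_rate_hz + 1e-9))
}

#' Per-sample boxcar mask of a condition
#'
#' Marks every sample falling inside one of the condition's half-open
#' `[onset, offset)` intervals: sample `i` (0-based) is active iff
#' `i / sampling_rate` lies in an interval.
#'
#' @param protocol a [protocol()] object.
#' @param condition_name condition to mask.
#' @param n_samples series length; defaults to the full protocol duration.
#' @return logical vector of length `n_samples`.
#' @export
condition_mask <- function(protocol, condition_name,
                           n_samples = protocol_n_samples(protocol)) {
  iv <- protocol$conditions[[condition_name]]
  if (is.null(iv)) stop(sprintf("unknown condition '%s'", condition_name))
  t_s <- (seq_len(n_samples) - 1L) / protocol$sampling_rate_hz
  mask <- rep(FALSE, n_samples)
  for (k in seq_len(nrow(iv))) {
    mask <- mask | (t_s >= iv[k, 1L] & t_s < iv[k, 2L])
  }
  mask
}

#' Trial intervals of a condition
#'
#' Each block interval of the condition is one trial.
#'
#' @inheritParams condition_mask
#' @return two-column matrix of `[onset, offset)` times in seconds.
#' @export
condition_trials <- function(protocol, condition_name) {
  iv <- protocol$conditions[[condition_name]]
  if (is.null(iv)) stop(sprintf("unknown condition '%s'", condition_name))
  iv
}

#' Read / write a protocol file
#'
#' Plain-text format. Header lines `sampling_rate_hz <v>` and
#' `total_duration_s <v>`, then one `condition <name>` line per condition
#' followed by `interval <onset_s> <offset_s>` lines. `#` starts a comment.
#'
#' @param path file path.
#' @return `read_protocol()` returns a [protocol()]; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fs <- NA_real_
  dur <- NA_real_
  conds <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    key <- tok[1L]
    if (key == "sampling_rate_hz") {
      fs <- as.numeric(tok[2L])
    } else if (key == "total_duration_s") {
      dur <- as.numeric(tok[2L])
    } else if (key == "condition") {
      if (length(tok) < 2L) stop(sprintf("%s:%d: condition line without name", path, i))
      current <- paste(tok[-1L], collapse = " ")
      conds[[current]] <- matrix(numeric(0), ncol = 2L)
    } else if (key == "interval") {
      if (is.null(current)) stop(sprintf("%s:%d: interval before any condition", path, i))
      v <- suppressWarnings(as.numeric(tok[2:3]))
      if (length(tok) != 3L || anyNA(v)) {
        stop(sprintf("%s:%d: malformed interval line", path, i))
      }
      conds[[current]] <- rbind(conds[[current]], v)
    } else {
      stop(sprintf("%s:%d: unknown key '%s'", path, i, key))
    }
  }
  if (!is.finite(fs)) stop(sprintf("%s: missing sampling_rate_hz", path))
  if (!is.finite(dur)) stop(sprintf("%s: missing total_duration_s", path))
  protocol(fs, conds, dur)
}

#' @rdname read_protocol
#' @param protocol a [protocol()] object.
#' @export
write_protocol <- function(protocol, path) {
  fmt <- function(v) format(v, trim = TRUE, digits = 15)
  lines <- c(
    "# rtnirs protocol",
    paste("sampling_rate_hz", fmt(protocol$sampling_rate_hz)),
    paste("total_duration_s", fmt(protocol$total_duration_s))
  )
  for (nm in names(protocol$conditions)) {
    iv <- protocol$conditions[[nm]]
    lines <- c(lines, paste("condition", nm))
    if (nrow(iv)) {
      lines <- c(lines, sprintf("interval %s %s", fmt(iv[, 1L]), fmt(iv[, 2L])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Streaming recording configuration
#'
#' Holds the two measurement wavelengths and the sample window used to
#' compute the hemoglobin baseline from raw intensities. The default
#' window is the first 200 received samples.
#'
#' @param wavelengths_nm the two wavelengths in nm.
#' @param hb_baseline_begin,hb_baseline_end half-open baseline window
#'   `[begin, end)` in 0-based sample indices.
#' @return an object of class `"recording_config"`.
#' @export
recording_config <- function(wavelengths_nm = c(760, 850),
                             hb_baseline_begin = 0L,
                             hb_baseline_end = 200L) {
  if (length(wavelengths_nm) != 2L || wavelengths_nm[1L] == wavelengths_nm[2L]) {
    stop("exactly two distinct wavelengths are required")
  }
  if (hb_baseline_begin < 0L || hb_baseline_begin >= hb_baseline_end) {
    stop("baseline window must satisfy 0 <= begin < end")
  }
  structure(
    list(
      n_wavelengths = 2L,
      wavelengths_nm = as.numeric(wavelengths_nm),
      hb_baseline_begin = as.integer(hb_baseline_begin),
      hb_baseline_end = as.integer(hb_baseline_end)
    ),
    class = "recording_config"
  )
}
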