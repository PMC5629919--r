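#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text format (one setting per line, `#` comments),
#' chosen so round-trips are bit-exact. Unknown keys are rejected with
#' the offending key named. See [pipeline_config()] for the keys.
#'
#' @param path file path.
#' @return `read_config()` returns a named list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (ln == "") next
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)[ \t]*=[ \t]*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop(sprintf("%s:%d: malformed config line", path, i))
    out[[kv[2L]]] <- kv[3L]
  }
  do.call(pipeline_config, out)
}

#' @rdname read_config
#' @param config a [pipeline_config()] list.
#' @export
write_config <- function(config, path) {
  ks <- names(config)
  vals <- vapply(config, function(v) paste(format(v, trim = TRUE, digits = 15),
                                           collapse = ","), character(1))
  writeLines(c("# rtnirs pipeline configuration", paste(ks, "=", vals)), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Aggregates the settings of every processing stage. All values may be
#' given as strings (as read from a config file); they are coerced and
#' validated here. Unknown keys are rejected.
#'
#' @param ... configuration keys: `raw_wl1`, `raw_wl2`, `montage`,
#'   `protocol` (paths), `out_dir`, `baseline_begin`, `baseline_end`
#'   (samples), `detrend_raw` (0/1), `ma_window` (samples, 0 = off),
#'   `ma_order` (1-5), `filter_family`, `filter_kind`, `filter_order`,
#'   `filter_cutoff_hz` (comma-separated for band kinds), `ripple_db`,
#'   `stopband_db`, `motion_correction` (0/1), `glm_trend` (0/1),
#'   `record_betas` (0/1), `seed`.
#' @return validated named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  given <- list(...)
  defaults <- list(
    raw_wl1 = NA, raw_wl2 = NA, montage = NA, protocol = NA,
    out_dir = ".", baseline_begin = 0, baseline_end = 200,
    detrend_raw = 0, ma_window = 0, ma_order = 1,
    filter_family = "", filter_kind = "low-pass", filter_order = 2,
    filter_cutoff_hz = "", ripple_db = 1, stopband_db = 40,
    motion_correction = 0, glm_trend = 0, record_betas = 0, seed = 1
  )
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, given)
  num_keys <- c("baseline_begin", "baseline_end", "detrend_raw", "ma_window",
                "ma_order", "filter_order", "ripple_db", "stopband_db",
                "motion_correction", "glm_trend", "record_betas", "seed")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  structure(cfg, class = c("pipeline_config", "list"))
}

config_filter <- function(cfg, fs) {
  if (!nzchar(cfg$filter_family)) return(NULL)
  cutoff <- as.numeric(strsplit(as.character(cfg$filter_cutoff_hz), ",")[[1L]])
  design_filter(filter_spec(
    family = cfg$filter_family, kind = cfg$filter_kind,
    order = cfg$filter_order, cutoff_hz = cutoff, sampling_rate_hz = fs,
    ripple_db = cfg$ripple_db, stopband_db = cfg$stopband_db
  ))
}

#' Offline (batch) analysis of a full recording
#'
#' Runs the complete pipeline on an already-recorded session: raw
#' preprocessing (optional causal detrend and moving-average
#' smoothing), streaming MBLL conversion, the configured IIR filter on
#' HbO and Hb, optional motion correction, and the recursive GLM.
#' Every stage is the same strictly causal operation used sample by
#' sample in streaming mode, so the offline result is identical to a
#' replayed real-time analysis.
#'
#' @param raw list with matrices `wl1`, `wl2`.
#' @param montage a [montage()].
#' @param protocol a [protocol()].
#' @param config a [pipeline_config()].
#' @return list with `conc` (filtered HbO/Hb matrices), `raw_pre`
#'   (preprocessed raw), `fit` (the [rlsglm()]), `design`, and `alpha`
#'   (motion-correction ratios or `NULL`).
#' @export
run_offline <- function(raw, montage, protocol, config = pipeline_config()) {
  fs <- protocol$sampling_rate_hz
  pre <- raw
  if (config$detrend_raw > 0) {
    pre <- list(wl1 = detrend_stream(pre$wl1)$y, wl2 = detrend_stream(pre$wl2)$y)
  }
  if (config$ma_window > 0) {
    pre <- list(
      wl1 = moving_average_lowpass(pre$wl1, config$ma_window, config$ma_order),
      wl2 = moving_average_lowpass(pre$wl2, config$ma_window, config$ma_order)
    )
  }
  rc <- recording_config(
    hb_baseline_begin = config$baseline_begin,
    hb_baseline_end = config$baseline_end
  )
  conc <- stream_convert(raw, rc, montage = montage)
  hbo <- zero_na(conc$hbo) # invalid channels carry zeros while processing
  hb <- zero_na(conc$hb)
  filt <- config_filter(config, fs)
  if (!is.null(filt)) {
    hbo <- filter_stream(filt, hbo)
    hb <- filter_stream(filt, hb)
  }
  alpha <- NULL
  if (config$motion_correction > 0) {
    mc <- motion_correct(hbo, hb)
    hbo <- mc$hbo
    hb <- mc$hb
    alpha <- mc$alpha
  }
  X <- build_design(protocol, nrow(hbo), include_trend = config$glm_trend > 0)
  fit <- rlsglm(X, hbo, record = config$record_betas > 0)
  hbo[, !conc$valid] <- NA_real_
  hb[, !conc$valid] <- NA_real_
  list(
    conc = list(hbo = hbo, hb = hb, valid = conc$valid),
    raw_pre = pre, fit = fit, design = X, alpha = alpha
  )
}

# invalid (flagged) channels are carried as zeros through the linear
# stages and restored to NA in the returned series
zero_na <- function(m) {
  m[!is.finite(m)] <- 0
  m
}

#' Replay a recorded raw matrix as a frame stream
#'
#' Returns an iterator that delivers the recording frame by frame,
#' exactly once and in order, emulating a live acquisition without
#' hardware.
#'
#' @param raw list with matrices `wl1`, `wl2`.
#' @return a function; each call returns the next
#'   `list(wl1 = <row>, wl2 = <row>, frame = <index>)`, or `NULL` after
#'   the last frame.
#' @export
replay_stream <- function(raw) {
  check_raw(raw)
  i <- 0L
  n <- nrow(raw$wl1)
  function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    list(wl1 = raw$wl1[i, ], wl2 = raw$wl2[i, ], frame = i)
  }
}

#' Frame-by-frame streaming analysis engine
#'
#' `stream_engine()` creates a stateful processor; `stream_feed()`
#' advances it by one raw frame. The engine buffers raw frames until
#' the baseline window completes, then converts retroactively and
#' emits, for every frame, the filtered (and optionally
#' motion-corrected) concentrations while advancing the recursive GLM.
#' Fed the frames of [replay_stream()], it produces output identical
#' to [run_offline()] on the whole recording.
#'
#' @param montage a [montage()].
#' @param protocol a [protocol()].
#' @param config a [pipeline_config()].
#' @param n_samples design length (defaults to the protocol duration).
#' @return an environment holding the engine state.
#' @export
stream_engine <- function(montage, protocol, config = pipeline_config(),
                          n_samples = protocol_n_samples(protocol)) {
  env <- new.env(parent = emptyenv())
  env$montage <- montage
  env$protocol <- protocol
  env$config <- config
  env$rc <- recording_config(hb_baseline_begin = config$baseline_begin,
                             hb_baseline_end = config$baseline_end)
  env$ext <- extinction_table()
  env$Einv <- solve(env$ext$E)
  env$filt <- config_filter(config, protocol$sampling_rate_hz)
  env$filt_state_hbo <- NULL
  env$filt_state_hb <- NULL
  env$mc_state <- NULL
  env$buffer <- list(wl1 = NULL, wl2 = NULL) # pre-baseline raw frames
  env$baseline <- NULL
  env$t <- 0L
  env$X <- build_design(protocol, n_samples, include_trend = config$glm_trend > 0)
  env$fit <- NULL
  nch <- n_channels(montage)
  env$hbo <- matrix(NA_real_, 0L, nch)
  env$hb <- matrix(NA_real_, 0L, nch)
  env
}

convert_frames <- function(env, wl1, wl2) {
  nch <- ncol(wl1)
  dist <- env$montage$distance_cm
  hbo <- matrix(NA_real_, nrow(wl1), nch)
  hb <- hbo
  for (ci in seq_len(nch)) {
    if (!env$baseline$valid[ci]) next
    s1 <- to_optical_density(wl1[, ci], env$baseline$I0_wl1[ci]) /
      (dist[ci] * env$ext$dpf[1L])
    s2 <- to_optical_density(wl2[, ci], env$baseline$I0_wl2[ci]) /
      (dist[ci] * env$ext$dpf[2L])
    hbo[, ci] <- env$Einv[1L, 1L] * s1 + env$Einv[1L, 2L] * s2
    hb[, ci] <- env$Einv[2L, 1L] * s1 + env$Einv[2L, 2L] * s2
  }
  list(hbo = hbo, hb = hb)
}

#' @rdname stream_engine
#' @param env a [stream_engine()] environment.
#' @param frame one frame from [replay_stream()].
#' @return `stream_feed()` returns (invisibly) the rows emitted for this
#'   frame: 0 rows before baseline completion, the whole retroactive
#'   block at completion, 1 row afterwards.
#' @export
stream_feed <- function(env, frame) {
  env$t <- env$t + 1L
  w1 <- matrix(frame$wl1, nrow = 1L)
  w2 <- matrix(frame$wl2, nrow = 1L)
  emitted <- NULL
  if (is.null(env$baseline)) {
    env$buffer$wl1 <- rbind(env$buffer$wl1, w1)
    env$buffer$wl2 <- rbind(env$buffer$wl2, w2)
    if (env$t >= env$rc$hb_baseline_end) {
      env$baseline <- compute_baseline(env$buffer, env$rc)
      emitted <- convert_frames(env, env$buffer$wl1, env$buffer$wl2)
    }
  } else {
    emitted <- convert_frames(env, w1, w2)
  }
  if (is.null(emitted)) return(invisible(NULL))
  hbo <- zero_na(emitted$hbo)
  hb <- zero_na(emitted$hb)
  if (!is.null(env$filt)) {
    so <- apply_filter(env$filt, hbo, env$filt_state_hbo)
    sh <- apply_filter(env$filt, hb, env$filt_state_hb)
    env$filt_state_hbo <- so$state
    env$filt_state_hb <- sh$state
    hbo <- so$y
    hb <- sh$y
  }
  if (env$config$motion_correction > 0) {
    mc <- motion_correct(hbo, hb, env$mc_state)
    env$mc_state <- mc$state
    hbo <- mc$hbo
    hb <- mc$hb
  }
  rows <- seq.int(nrow(env$hbo) + 1L, nrow(env$hbo) + nrow(hbo))
  env$hbo <- rbind(env$hbo, hbo)
  env$hb <- rbind(env$hb, hb)
  Xrows <- env$X[rows, , drop = FALSE]
  if (is.null(env$fit)) {
    env$fit <- rlsglm(Xrows, hbo, record = env$config$record_betas > 0)
  } else {
    env$fit <- update(env$fit, Xrows, hbo)
  }
  invisible(list(hbo = hbo, hb = hb))
}

#' @rdname stream_engine
#' @return `stream_result()` returns the accumulated output of a
#'   streamed session in the same form as [run_offline()].
#' @export
stream_result <- function(env) {
  hbo <- env$hbo
  hb <- env$hb
  if (!is.null(env$baseline)) {
    hbo[, !env$baseline$valid] <- NA_real_
    hb[, !env$baseline$valid] <- NA_real_
  }
  list(
    conc = list(hbo = hbo, hb = hb,
                valid = if (is.null(env$baseline)) NULL else env$baseline$valid),
    fit = env$fit
  )
}

#' Request/response dispatcher for external stimulus software
#'
#' Implements the line-based text protocol that stimulus-presentation
#' software uses to poll the running analysis. Commands:
#' `get_feedback` (latest feedback value), `get_level` (latest
#' thermometer level), `get_beta <channel> <predictor>` (current GLM
#' coefficient), `status` (sample counter). Unknown commands yield an
#' `ERR` line; the connection stays usable.
#'
#' @param state list/environment with (any of) `fb` (latest feedback
#'   value), `level` (latest thermometer level), `fit` (an
#'   [rlsglm()]), and `t` (sample counter).
#' @param line one request line.
#' @return one response line (character scalar).
#' @export
nf_handle_request <- function(state, line) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (!length(tok)) return("ERR empty request")
  cmd <- tok[1L]
  if (cmd == "get_feedback") {
    if (is.null(state$fb)) return("ERR no feedback yet")
    sprintf("%.10g", state$fb)
  } else if (cmd == "get_level") {
    if (is.null(state$level)) return("0")
    sprintf("%d", as.integer(state$level))
  } else if (cmd == "get_beta") {
    if (is.null(state$fit) || is.na(state$fit$initialized_at)) {
      return("ERR glm not initialized")
    }
    ch <- suppressWarnings(as.integer(tok[2L]))
    pr <- suppressWarnings(as.integer(tok[3L]))
    if (is.na(ch) || is.na(pr) || ch < 1L || ch > state$fit$n_channels ||
        pr < 1L || pr > state$fit$p) {
      return("ERR bad channel/predictor index")
    }
    sprintf("%.10g", coef(state$fit)[pr, ch])
  } else if (cmd == "status") {
    sprintf("OK t=%d", if (is.null(state$t)) 0L else as.integer(state$t))
  } else {
    sprintf("ERR unknown command '%s'", cmd)
  }
}

#' Serve the request/response protocol on a TCP port
#'
#' Thin blocking loop around [nf_handle_request()]: accepts one client
#' at a time, answers line requests until the client disconnects or
#' `"quit"` is received. Intended for interactive use with stimulus
#' software; all protocol logic lives in the testable dispatcher.
#'
#' @param state see [nf_handle_request()].
#' @param port TCP port.
#' @param max_requests stop after this many requests (default
#'   unlimited).
#' @export
nf_serve <- function(state, port = 55555L, max_requests = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0
  repeat {
    con <- socketAccept(srv, blocking = TRUE, open = "r+")
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line) || identical(line, "quit")) break
      writeLines(nf_handle_request(state, line), con)
      flush(con)
      served <- served + 1
      if (served >= max_requests) break
    }
    close(con)
    if (served >= max_requests) break
  }
  invisible(served)
}
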